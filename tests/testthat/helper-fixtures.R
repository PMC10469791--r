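# Shared fixtures and independent oracles, built in code at test time.

tiny_montage <- function() make_montage(c("C1", "C2", "C3", "C4"))

# small epoch set with known content
tiny_epochs <- function(n_trials = 6L, n_channels = 4L, n_samples = 64L,
                        fs = 128, seed = 1L, montage = tiny_montage()) {
  set.seed(seed)
  data <- array(rnorm(n_trials * n_channels * n_samples),
                dim = c(n_trials, n_channels, n_samples))
  make_epochs(data, fs,
              labels = rep_len(0:1, n_trials),
              sessions = rep(1L, n_trials), montage)
}

# model config small enough for exhaustive probing
tiny_model_config <- function(...) {
  model_config(n_channels = 4L, n_samples = 40L, n_classes = 2L,
               temporal = list(n_filters = 2L, kernel_len = 5L,
                               pool_len = 10L, pool_stride = 5L),
               n_heads = 2L, token_embed_dim = 4L,
               spatial = list(n_filters_per_path = 2L),
               tdense = list(n_layers_per_branch = 3L, growth = 4L,
                             reduce_filters = 4L, kernel_len = 3L),
               dropout_rate = 0, seed = 7L, ...)
}

tiny_bands <- function(N = 3L, Tt = 40L, C = 4L, seed = 1L) {
  set.seed(seed)
  lapply(1:3, function(b) array(rnorm(Tt * C * N), dim = c(Tt, C, N)))
}

# independent brute-force attention oracle: explicit softmax loop
oracle_attention <- function(Q, K, V, mask = NULL) {
  n <- nrow(Q)
  m <- nrow(K)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    e <- numeric(m)
    for (j in seq_len(m)) e[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(Q))
    if (!is.null(mask)) e[!mask[i, ]] <- -Inf
    w <- exp(e - max(e))
    w <- w / sum(w)
    for (j in seq_len(m)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# multiband wrapper around raw arrays for training tests
quick_multiband <- function(epochs) make_multiband(epochs)

# sinusoid epochs: every channel the same pure tone
sine_epochs <- function(freq, fs = 250, n_samples = 1000L, n_trials = 2L,
                        montage = tiny_montage(), amplitude = 1) {
  tvec <- seq_len(n_samples) / fs
  chan <- amplitude * sin(2 * pi * freq * tvec)
  data <- array(rep(chan, each = n_trials * length(montage$channel_names)),
                dim = c(n_trials, length(montage$channel_names), n_samples))
  for (i in seq_len(n_trials))
    for (c in seq_along(montage$channel_names))
      data[i, c, ] <- chan
  make_epochs(data, fs, labels = rep(0L, n_trials),
              sessions = rep(1L, n_trials), montage)
}

# dominant FFT frequency of a vector
dominant_freq <- function(x, fs) {
  spec <- Mod(stats::fft(x))[seq_len(floor(length(x) / 2))]
  spec[1] <- 0                          # ignore DC
  (which.max(spec) - 1) * fs / length(x)
}
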