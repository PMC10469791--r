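#' Synthetic lateralized-EEG configuration
#'
#' Generative parameters of the synthetic motor-imagery model. Each trial is
#' 1/f ("pink") background noise on every channel plus ongoing mu (~10 Hz)
#' and beta (~20 Hz) oscillations; for hand-imagery classes the oscillation
#' amplitude over the hemisphere CONTRALATERAL to the imagined hand is
#' multiplied by `sqrt(1 - erd_depth)`, i.e. its band power by
#' `1 - erd_depth`, emulating event-related desynchronization. In four-class
#' mode, class 2 ("feet") attenuates midline beta power and class 3
#' ("tongue") attenuates mu power on all channels -- a toy convention, not
#' physiology.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions 1 or 2 recording sessions per subject.
#' @param trials_per_session trials per session (balanced over classes).
#' @param n_classes 2 (left/right hand) or 4 (+ feet, tongue).
#' @param fs sampling rate (Hz).
#' @param duration trial length (s); `fs * duration` must be integral.
#' @param montage electrode montage (default the 20-channel motor set).
#' @param erd_depth fractional band-power attenuation in `[0, 1)`.
#' @param background_amp RMS amplitude (microvolt) of the pink background.
#' @param mu_amp,beta_amp oscillation amplitudes (microvolt).
#' @param pink_exponent spectral slope of the 1/f background.
#' @param session_drift list `gain_sd` (SD of multiplicative per-channel
#'   gains applied to session 2) and `freq_jitter_hz` (SD of a session-2
#'   shift of the mu center frequency).
#' @param subject_gain_sd SD of per-subject global gain.
#' @param seed root seed; the full dataset is reproducible from it.
#' @return An object of class `lgct_synth_config`.
#' @export
synth_config <- function(n_subjects = 1L, n_sessions = 2L,
                         trials_per_session = 200L, n_classes = 2L,
                         fs = 250, duration = 4,
                         montage = ku_motor_montage(),
                         erd_depth = 0.8, background_amp = 5,
                         mu_amp = 12, beta_amp = 6,
                         pink_exponent = 1,
                         session_drift = list(gain_sd = 0.2,
                                              freq_jitter_hz = 0.5),
                         subject_gain_sd = 0.1, seed = 1L) {
  stopifnot(n_sessions %in% 1:2, n_classes %in% c(2L, 4L),
            erd_depth >= 0, erd_depth < 1)
  n_samp <- fs * duration
  if (abs(n_samp - round(n_samp)) > 1e-9) stop("fs * duration must be integral")
  validate_montage(montage)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 n_classes = as.integer(n_classes), fs = fs,
                 duration = duration, montage = montage,
                 erd_depth = erd_depth, background_amp = background_amp,
                 mu_amp = mu_amp, beta_amp = beta_amp,
                 pink_exponent = pink_exponent,
                 session_drift = session_drift,
                 subject_gain_sd = subject_gain_sd,
                 seed = as.integer(seed)),
            class = "lgct_synth_config")
}

# spectrally shaped white noise: PSD ~ 1/f^exponent, scaled to unit RMS
pink_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                     # DC bin kept at weight of f=1
  f <- pmin(f, n - f + 1)                       # mirror for negative freqs
  spec <- spec * (1 / f^(exponent / 2))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate one synthetic motor-imagery trial
#'
#' Uses the current R random-number-generator state; seed it (or call via
#' [generate_dataset()]) for reproducibility.
#'
#' @param cls 0-based class id (0 = left hand, 1 = right hand, 2 = feet,
#'   3 = tongue).
#' @param cfg a [synth_config()].
#' @param channel_gain optional per-channel multiplicative gains (drift).
#' @param mu_shift_hz optional shift of the mu center frequency (drift).
#' @return A `channels x samples` matrix (microvolt).
#' @export
generate_trial <- function(cls, cfg, channel_gain = NULL, mu_shift_hz = 0) {
  m <- cfg$montage
  C <- length(m$channel_names)
  n <- as.integer(round(cfg$fs * cfg$duration))
  if (is.null(channel_gain)) channel_gain <- rep(1, C)
  stopifnot(cls >= 0L, cls < cfg$n_classes)
  tvec <- seq_len(n) / cfg$fs
  # per-channel band-power attenuation factors
  mu_att <- rep(1, C)
  beta_att <- rep(1, C)
  d <- cfg$erd_depth
  if (cls == 0L) {            # left hand -> contralateral = right hemisphere
    mu_att[m$right_idx] <- 1 - d
    beta_att[m$right_idx] <- 1 - d
  } else if (cls == 1L) {     # right hand -> left hemisphere
    mu_att[m$left_idx] <- 1 - d
    beta_att[m$left_idx] <- 1 - d
  } else if (cls == 2L) {     # feet -> midline beta
    beta_att[m$midline_idx] <- 1 - d
  } else {                    # tongue -> broadband mu everywhere
    mu_att[] <- 1 - d
  }
  f_mu <- stats::rnorm(1, 10 + mu_shift_hz, 0.3)
  f_beta <- stats::rnorm(1, 20, 0.5)
  x <- matrix(0, C, n)
  for (c in seq_len(C)) {
    bg <- cfg$background_amp * pink_noise(n, cfg$pink_exponent)
    mu <- cfg$mu_amp * sqrt(mu_att[c]) *
      sin(2 * pi * f_mu * tvec + stats::runif(1, 0, 2 * pi))
    beta <- cfg$beta_amp * sqrt(beta_att[c]) *
      sin(2 * pi * f_beta * tvec + stats::runif(1, 0, 2 * pi))
    x[c, ] <- channel_gain[c] * (bg + mu + beta)
  }
  x
}

#' Generate a full synthetic dataset
#'
#' Per subject: a random global gain, then `n_sessions` sessions of
#' `trials_per_session` trials with balanced, seeded-shuffled labels.
#' Session 2 is perturbed by the configured drift (per-channel gains and a mu
#' frequency shift), emulating the between-day change of statistical
#' distributions. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return An object of class `lgct_synth_dataset`: list with `epochs` (one
#'   `lgct_epochs` per subject, sessions concatenated), `truth` (generative
#'   parameters per subject) and `cfg`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "lgct_synth_config"))
  set.seed(cfg$seed)
  C <- length(cfg$montage$channel_names)
  n <- as.integer(round(cfg$fs * cfg$duration))
  subjects <- vector("list", cfg$n_subjects)
  truth <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    subj_gain <- exp(stats::rnorm(1, 0, cfg$subject_gain_sd))
    data_list <- list()
    labels <- integer(0)
    sessions <- integer(0)
    drift <- list(gain = rep(1, C), mu_shift = 0)
    for (sess in seq_len(cfg$n_sessions)) {
      if (sess == 2L) {
        drift <- list(
          gain = exp(stats::rnorm(C, 0, cfg$session_drift$gain_sd)),
          mu_shift = stats::rnorm(1, 0, cfg$session_drift$freq_jitter_hz))
      }
      lab <- rep_len(seq_len(cfg$n_classes) - 1L, cfg$trials_per_session)
      lab <- sample(lab)
      arr <- array(0, dim = c(cfg$trials_per_session, C, n))
      for (i in seq_len(cfg$trials_per_session)) {
        arr[i, , ] <- generate_trial(lab[i], cfg,
                                     channel_gain = subj_gain * drift$gain,
                                     mu_shift_hz = drift$mu_shift)
      }
      data_list[[sess]] <- arr
      labels <- c(labels, lab)
      sessions <- c(sessions, rep(sess, cfg$trials_per_session))
    }
    data <- do.call(abind1, data_list)
    subjects[[s]] <- make_epochs(data, cfg$fs, labels, sessions, cfg$montage)
    truth[[s]] <- list(subject_gain = subj_gain, session2_drift = drift)
  }
  structure(list(epochs = subjects, truth = truth, cfg = cfg),
            class = "lgct_synth_dataset")
}

# bind trial arrays along the first axis
abind1 <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L) return(parts[[1L]])
  d <- dim(parts[[1L]])
  out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1L], 1L)),
                          d[2L], d[3L]))
  off <- 0L
  for (p in parts) {
    out[off + seq_len(dim(p)[1L]), , ] <- p
    off <- off + dim(p)[1L]
  }
  out
}

#' Band power via Welch's method
#'
#' Mean power spectral density integrated over a frequency band, averaged
#' over Hann-windowed overlapping segments. Used by the package's tests as an
#' independent check of the generator's ERD structure.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param band length-2 vector of band edges (Hz).
#' @param seg_len segment length in samples.
#' @return Scalar band power.
#' @export
band_power <- function(x, fs, band, seg_len = 256L) {
  seg_len <- min(seg_len, length(x))
  step <- seg_len %/% 2L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  psd <- rep(0, seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * win
    psd <- psd + Mod(stats::fft(seg))^2
  }
  psd <- psd / (length(starts) * sum(win^2) * fs)
  freqs <- (seq_len(seg_len) - 1) * fs / seg_len
  sel <- freqs >= band[1L] & freqs <= band[2L]
  2 * sum(psd[sel]) * fs / seg_len
}
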