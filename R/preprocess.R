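#' Frequency band specification
#'
#' @param name band label (e.g. `"alpha"`).
#' @param low,high band edges in Hz, or `NULL`/`NULL` for the raw passthrough
#'   band. When both are given, `0 < low < high` is required (the Nyquist check
#'   happens against the epoch set at filter time).
#' @return An object of class `lgct_band`.
#' @export
band_spec <- function(name, low = NULL, high = NULL) {
  if (xor(is.null(low), is.null(high)))
    stop("band edges must be both NULL (raw) or both given")
  if (!is.null(low)) {
    stopifnot(is.numeric(low), is.numeric(high))
    if (!(low > 0 && low < high)) stop("band requires 0 < low < high")
  }
  structure(list(name = name, low = low, high = high), class = "lgct_band")
}

is_raw_band <- function(band) is.null(band$low)

#' Canonical three-band set: raw, mu/alpha (7-12 Hz), beta (13-32 Hz)
#' @return list of three [band_spec()] objects in fixed order.
#' @export
default_bands <- function() {
  list(band_spec("raw"),
       band_spec("alpha", 7, 12),
       band_spec("beta", 13, 32))
}

#' Select channels by label
#'
#' Restricts an epoch set to the given electrodes (in `keep` order) and
#' rebuilds the montage partition for the subset.
#'
#' @param epochs an `lgct_epochs`.
#' @param keep character vector of labels, all present in the montage.
#' @return The channel-restricted `lgct_epochs`.
#' @export
select_channels <- function(epochs, keep) {
  idx <- match(keep, epochs$montage$channel_names)
  if (anyNA(idx)) {
    stop("unknown channel label(s): ", paste(keep[is.na(idx)], collapse = ", "))
  }
  make_epochs(epochs$data[, idx, , drop = FALSE], epochs$fs,
              epochs$labels, epochs$sessions, make_montage(keep))
}

#' Downsample by an integer factor with anti-alias filtering
#'
#' Applies a zero-phase order-8 Butterworth low-pass at 0.8 x the target
#' Nyquist frequency, then keeps every `fs/target_fs`-th sample.
#'
#' @param epochs an `lgct_epochs`.
#' @param target_fs target sampling rate; `epochs$fs` must be an integer
#'   multiple of it.
#' @return The decimated `lgct_epochs` with updated `fs`.
#' @export
downsample <- function(epochs, target_fs) {
  q <- epochs$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("fs (", epochs$fs, ") is not an integer multiple of target_fs (",
         target_fs, "); rational-ratio resampling is not supported")
  q <- as.integer(round(q))
  if (q == 1L) return(epochs)
  bf <- signal::butter(8, 0.8 / q, type = "low")
  keep <- seq(1L, n_samples(epochs), by = q)
  out <- apply_filtfilt(epochs$data, bf)
  make_epochs(out[, , keep, drop = FALSE], target_fs,
              epochs$labels, epochs$sessions, epochs$montage)
}

#' Zero-phase band-pass filtering
#'
#' Applies a forward-backward (zero-phase) order-4 Butterworth band-pass to
#' every trial and channel. The raw passthrough band returns the input
#' unchanged.
#'
#' @param epochs an `lgct_epochs`.
#' @param band a [band_spec()].
#' @return Filtered `lgct_epochs` with unchanged dimensions.
#' @export
bandpass <- function(epochs, band) {
  stopifnot(inherits(band, "lgct_band"))
  if (is_raw_band(band)) return(epochs)
  nyq <- epochs$fs / 2
  if (band$high >= nyq)
    stop("band edge ", band$high, " Hz >= Nyquist (", nyq, " Hz)")
  bf <- signal::butter(4, c(band$low, band$high) / nyq, type = "pass")
  out <- apply_filtfilt(epochs$data, bf)
  make_epochs(out, epochs$fs, epochs$labels, epochs$sessions, epochs$montage)
}

# filtfilt over the sample axis of a trials x channels x samples array
apply_filtfilt <- function(data, bf) {
  d <- dim(data)
  # flatten (trial, channel) into rows for a single vapply pass
  flat <- matrix(aperm(data, c(3L, 1L, 2L)), nrow = d[3L])
  filt <- vapply(seq_len(ncol(flat)),
                 function(j) signal::filtfilt(bf, flat[, j]),
                 numeric(d[3L]))
  aperm(array(filt, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
}

#' Per-trial, per-channel Z-score normalization
#'
#' Each channel time series of each trial is centred by its mean and scaled by
#' its population standard deviation (divide by N, no Bessel correction), the
#' standardization `z = (x - mu) / sigma` applied channel-wise.
#'
#' @param epochs an `lgct_epochs`.
#' @return Standardized `lgct_epochs`; every (trial, channel) series has mean 0
#'   and population SD 1.
#' @export
zscore <- function(epochs) {
  d <- dim(epochs$data)
  x <- epochs$data
  mu <- rowMeans(x, dims = 2L)               # trials x channels
  xc <- x - as.vector(mu)                    # recycles over sample axis
  sd_pop <- sqrt(rowMeans(xc^2, dims = 2L))
  if (any(sd_pop == 0)) {
    w <- which(sd_pop == 0, arr.ind = TRUE)[1L, ]
    stop("zero-variance channel: trial ", w[1L], ", channel ",
         epochs$montage$channel_names[w[2L]])
  }
  make_epochs(xc / as.vector(sd_pop), epochs$fs, epochs$labels,
              epochs$sessions, epochs$montage)
}

#' Build the three-band model input
#'
#' Produces the fixed-order (raw, alpha, beta) multi-band input: each band is
#' band-pass filtered (raw passes through) and then Z-scored per trial and
#' channel.
#'
#' @param epochs a channel-selected, downsampled `lgct_epochs`.
#' @param bands list of three [band_spec()]s; defaults to [default_bands()].
#' @return An object of class `lgct_multiband`: a list with `bands` (the
#'   specs) and `epochs` (the per-band `lgct_epochs`, dimension-identical).
#' @export
make_multiband <- function(epochs, bands = default_bands()) {
  stopifnot(length(bands) == 3L)
  if (!is_raw_band(bands[[1L]]))
    stop("first band must be the raw passthrough")
  out <- lapply(bands, function(b) zscore(bandpass(epochs, b)))
  structure(list(bands = bands, epochs = out), class = "lgct_multiband")
}

#' @export
print.lgct_multiband <- function(x, ...) {
  cat("<lgct_multiband> bands:",
      paste(vapply(x$bands, `[[`, "", "name"), collapse = ", "), "\n")
  print(x$epochs[[1L]])
  invisible(x)
}

#' Subset trials of a multi-band input
#' @param mb an `lgct_multiband`.
#' @param idx trial indices.
#' @return An `lgct_multiband` restricted to `idx`.
#' @export
subset_multiband <- function(mb, idx) {
  structure(list(bands = mb$bands,
                 epochs = lapply(mb$epochs, subset_trials, idx = idx)),
            class = "lgct_multiband")
}
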