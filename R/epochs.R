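#' Epoched EEG trials
#'
#' The universal container passed between preprocessing, splitting and the
#' model: a `trials x channels x samples` numeric array plus sampling rate,
#' per-trial class labels, per-trial session ids and the montage.
#'
#' @param data numeric array with `dim = c(trials, channels, samples)`, in
#'   microvolts. Must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param labels integer vector of per-trial class labels in `0:(n_classes-1)`.
#' @param sessions integer vector of per-trial session ids (1-based).
#' @param montage an [make_montage()] object whose channel count matches
#'   `dim(data)[2]`.
#' @return An object of class `lgct_epochs`.
#' @export
make_epochs <- function(data, fs, labels, sessions, montage) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a trials x channels x samples array")
  if (!all(is.finite(data))) stop("data contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  n <- dim(data)[1L]
  labels <- as.integer(labels)
  sessions <- as.integer(sessions)
  if (length(labels) != n) stop("length(labels) != number of trials")
  if (length(sessions) != n) stop("length(sessions) != number of trials")
  if (any(labels < 0L)) stop("labels must be nonnegative 0-based class ids")
  validate_montage(montage)
  if (length(montage$channel_names) != dim(data)[2L])
    stop("montage has ", length(montage$channel_names),
         " channels but data has ", dim(data)[2L])
  structure(
    list(data = data, fs = as.numeric(fs), labels = labels,
         sessions = sessions, montage = montage),
    class = "lgct_epochs"
  )
}

#' @export
print.lgct_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lgct_epochs> %d trials x %d channels x %d samples @ %g Hz, %d classes, sessions {%s}\n",
              d[1], d[2], d[3], x$fs, length(unique(x$labels)),
              paste(sort(unique(x$sessions)), collapse = ",")))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1L]
n_channels <- function(epochs) dim(epochs$data)[2L]
n_samples <- function(epochs) dim(epochs$data)[3L]

#' Subset trials of an epoch set
#'
#' @param epochs an `lgct_epochs` object.
#' @param idx integer vector of trial indices (1-based).
#' @return An `lgct_epochs` restricted to the selected trials, in `idx` order.
#' @export
subset_trials <- function(epochs, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= n_trials(epochs)))
  make_epochs(epochs$data[idx, , , drop = FALSE], epochs$fs,
              epochs$labels[idx], epochs$sessions[idx], epochs$montage)
}
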