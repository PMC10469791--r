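#' Read / write a trials bundle
#'
#' The trials bundle is the package's plain fixture format: a directory with
#' `manifest.json` (schema version, `fs`, `channel_names`, `labels`,
#' `sessions`, `n_trials`, `n_channels`, `n_samples`, `dtype`) and `data.bin`
#' (little-endian 32-bit float, trial-major, channel-then-sample order within
#' each trial). Writing a bundle read from disk reproduces `data.bin`
#' byte-identically; note that writing converts double-precision data to
#' float32 once.
#'
#' @param epochs an `lgct_epochs`.
#' @param path bundle directory.
#' @return `write_trials_bundle` returns `path` invisibly;
#'   `read_trials_bundle` returns an `lgct_epochs`.
#' @export
write_trials_bundle <- function(epochs, path) {
  stopifnot(inherits(epochs, "lgct_epochs"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  manifest <- list(schema_version = 1L, fs = epochs$fs,
                   channel_names = epochs$montage$channel_names,
                   labels = epochs$labels, sessions = epochs$sessions,
                   n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
                   dtype = "float32_le")
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  # trial-major, channel-then-sample: trial slices written contiguously
  flat <- aperm(epochs$data, c(3L, 2L, 1L))   # samples, channels, trials
  writeBin(as.numeric(flat), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_trials_bundle
#' @export
read_trials_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$schema_version) || manifest$schema_version != 1L)
    stop("unsupported bundle schema version: ", manifest$schema_version)
  for (field in c("fs", "channel_names", "labels", "sessions", "n_trials",
                  "n_channels", "n_samples", "dtype"))
    if (is.null(manifest[[field]])) stop("manifest missing field: ", field)
  if (manifest$dtype != "float32_le")
    stop("unsupported bundle dtype: ", manifest$dtype)
  if (length(manifest$channel_names) != manifest$n_channels)
    stop("manifest schema error: ", length(manifest$channel_names),
         " channel names for n_channels = ", manifest$n_channels)
  bin <- file.path(path, "data.bin")
  n_expect <- manifest$n_trials * manifest$n_channels * manifest$n_samples
  if (file.info(bin)$size != 4L * n_expect)
    stop("data.bin truncated or oversized: ", file.info(bin)$size,
         " bytes, expected ", 4L * n_expect)
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n_expect, size = 4L, endian = "little")
  data <- aperm(array(vals, dim = c(manifest$n_samples, manifest$n_channels,
                                    manifest$n_trials)), c(3L, 2L, 1L))
  make_epochs(data, manifest$fs, manifest$labels, manifest$sessions,
              make_montage(manifest$channel_names))
}
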