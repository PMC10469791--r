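# Minimal EDF(+) writer used to build test fixtures in code.
# signals: channels x samples matrix; one data record per second.
write_edf_fixture <- function(path, signals, fs, labels,
                              annotations = NULL,
                              phys_range = c(-250, 250)) {
  stopifnot(nrow(signals) == length(labels), ncol(signals) %% fs == 0)
  n_records <- ncol(signals) / fs
  annot_spr <- 32L                       # 64 bytes per record
  ns <- nrow(signals) + if (is.null(annotations)) 0L else 1L
  pad <- function(x, n) {
    s <- substr(paste0(x, strrep(" ", n)), 1L, n)
    charToRaw(s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pad("0", 8L), con)
  writeBin(pad("test patient", 80L), con)
  writeBin(pad("test recording", 80L), con)
  writeBin(pad("01.01.24", 8L), con)
  writeBin(pad("00.00.00", 8L), con)
  writeBin(pad(as.character(256L * (1L + ns)), 8L), con)
  writeBin(pad(if (is.null(annotations)) "" else "EDF+C", 44L), con)
  writeBin(pad(as.character(n_records), 8L), con)
  writeBin(pad("1", 8L), con)            # record duration 1 s
  writeBin(pad(as.character(ns), 4L), con)
  all_labels <- c(labels, if (!is.null(annotations)) "EDF Annotations")
  for (lb in all_labels) writeBin(pad(lb, 16L), con)
  for (i in seq_len(ns)) writeBin(pad("", 80L), con)   # transducer
  for (i in seq_len(ns)) writeBin(pad("uV", 8L), con)
  for (i in seq_len(ns)) writeBin(pad(as.character(phys_range[1]), 8L), con)
  for (i in seq_len(ns)) writeBin(pad(as.character(phys_range[2]), 8L), con)
  for (i in seq_len(ns)) writeBin(pad("-32768", 8L), con)
  for (i in seq_len(ns)) writeBin(pad("32767", 8L), con)
  for (i in seq_len(ns)) writeBin(pad("", 80L), con)   # prefiltering
  sprs <- c(rep(fs, nrow(signals)), if (!is.null(annotations)) annot_spr)
  for (s in sprs) writeBin(pad(as.character(s), 8L), con)
  for (i in seq_len(ns)) writeBin(pad("", 32L), con)

  gain <- (phys_range[2] - phys_range[1]) / (32767 - (-32768))
  to_dig <- function(x) {
    as.integer(pmin(32767, pmax(-32768,
                                round((x - phys_range[1]) / gain - 32768))))
  }
  dc4 <- rawToChar(as.raw(0x14))
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nrow(signals)))
      writeBin(to_dig(signals[i, cols]), con, size = 2L, endian = "little")
    if (!is.null(annotations)) {
      tals <- paste0("+", r - 1L, dc4, dc4)  # record-start timekeeping TAL
      here <- annotations[annotations$onset >= r - 1L &
                            annotations$onset < r, , drop = FALSE]
      for (k in seq_len(nrow(here)))
        tals <- c(tals, paste0("+", format(here$onset[k]), dc4,
                               here$label[k], dc4))
      # nul-terminate each TAL, pad the record with nuls
      bytes <- unlist(lapply(tals, function(tt) c(charToRaw(tt),
                                                  as.raw(0L))))
      stopifnot(length(bytes) <= 2L * annot_spr)
      bytes <- c(bytes, as.raw(rep(0L, 2L * annot_spr - length(bytes))))
      writeBin(bytes, con)
    }
  }
  invisible(path)
}
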