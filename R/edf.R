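#' Read an EDF/EDF+ recording
#'
#' Minimal reader for the European Data Format: parses the fixed 256-byte
#' header plus per-signal headers and decodes the 16-bit little-endian data
#' records to physical units. Annotation channels ("EDF Annotations") are
#' parsed from their time-stamped annotation lists into an event table.
#'
#' @param path EDF file.
#' @param channels optional character vector restricting (and ordering) the
#'   returned signal channels by label.
#' @return A list with `signals` (channels x samples matrix), `labels`
#'   (channel labels), `fs` (sampling rate, Hz; all selected channels must
#'   share it) and `annotations` (data.frame `onset`, `duration`,
#'   `label`; empty if the file has no annotation channel).
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(nchar) trimws(rawToChar(readBin(con, "raw", nchar)))
  version <- hdr_chr(8L)
  if (!startsWith(version, "0")) stop("not an EDF file (version '",
                                      version, "')")
  hdr_chr(80L); hdr_chr(80L); hdr_chr(8L); hdr_chr(8L)   # ids, date, time
  header_bytes <- as.integer(hdr_chr(8L))
  hdr_chr(44L)                                           # reserved
  n_records <- as.integer(hdr_chr(8L))
  record_dur <- as.numeric(hdr_chr(8L))
  ns <- as.integer(hdr_chr(4L))
  field <- function(nchar) vapply(seq_len(ns), function(i) hdr_chr(nchar), "")
  labels <- field(16L)
  field(80L); field(8L)                                  # transducer, unit
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)                                             # prefiltering
  spr <- as.integer(field(8L))                           # samples per record
  field(32L)                                             # reserved
  seek(con, header_bytes)

  is_annot <- labels == "EDF Annotations"
  raw_records <- vector("list", ns)
  for (i in seq_len(ns)) raw_records[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        raw_records[[i]][[r]] <- readBin(con, "raw", 2L * spr[i])
      } else {
        raw_records[[i]][[r]] <- readBin(con, "integer", n = spr[i],
                                         size = 2L, signed = TRUE,
                                         endian = "little")
      }
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig_idx <- which(!is_annot)
  signals <- do.call(rbind, lapply(sig_idx, function(i) {
    dig <- unlist(raw_records[[i]])
    phys_min[i] + gain[i] * (dig - dig_min[i])
  }))
  rownames(signals) <- labels[sig_idx]
  fs_all <- spr[sig_idx] / record_dur
  annotations <- parse_edf_annotations(raw_records[is_annot])
  if (!is.null(channels)) {
    miss <- setdiff(channels, labels[sig_idx])
    if (length(miss)) stop("channel(s) not in EDF: ",
                           paste(miss, collapse = ", "))
    keep <- match(channels, labels[sig_idx])
    signals <- signals[keep, , drop = FALSE]
    fs_all <- fs_all[keep]
  }
  if (length(unique(fs_all)) > 1L)
    stop("selected channels have mixed sampling rates: ",
         paste(unique(fs_all), collapse = ", "))
  list(signals = signals, labels = rownames(signals), fs = fs_all[1L],
       annotations = annotations)
}

# decode time-stamped annotation lists (TALs): each is
# "+<onset>[<DC4><duration>]<DC4><label><DC4>..." terminated by a nul byte
parse_edf_annotations <- function(annot_records) {
  out <- data.frame(onset = numeric(), duration = numeric(),
                    label = character())
  dc4 <- rawToChar(as.raw(0x14))
  dc5 <- rawToChar(as.raw(0x15))
  for (chan in annot_records) {
    bytes <- unlist(chan)
    # split the byte stream on nul terminators before text conversion
    groups <- split(bytes, cumsum(bytes == as.raw(0L)))
    tals <- vapply(groups, function(g) {
      g <- g[g != as.raw(0L)]
      if (length(g)) rawToChar(g) else ""
    }, "")
    for (tal in tals) {
      if (!nzchar(tal)) next
      parts <- strsplit(tal, dc4, fixed = TRUE)[[1L]]
      head <- strsplit(parts[1L], dc5, fixed = TRUE)[[1L]]
      onset <- suppressWarnings(as.numeric(head[1L]))
      if (is.na(onset)) next
      duration <- if (length(head) > 1L)
        suppressWarnings(as.numeric(head[2L])) else NA_real_
      labs <- parts[-1L]
      labs <- labs[nzchar(labs)]
      for (lb in labs)
        out <- rbind(out, data.frame(onset = onset, duration = duration,
                                     label = lb))
    }
  }
  out
}

#' Epoch a continuous EDF recording around cue events
#'
#' Cuts `[cue, cue + duration)` windows from the continuous signals. Events
#' come either from the EDF+ annotations or from an external table.
#'
#' @param edf a [read_edf()] result.
#' @param events data.frame with `onset` (seconds) and `label` (class id or
#'   name); defaults to the EDF's own annotations.
#' @param duration epoch length in seconds.
#' @param label_map optional named vector mapping event labels to 0-based
#'   class ids; unmapped events are dropped. Without it, labels must already
#'   be integers.
#' @param session session id assigned to all trials.
#' @return An `lgct_epochs`.
#' @export
epoch_edf <- function(edf, events = NULL, duration = 4,
                      label_map = NULL, session = 1L) {
  if (is.null(events)) events <- edf$annotations
  if (nrow(events) == 0L) stop("no events to epoch around")
  if (!is.null(label_map)) {
    keep <- events$label %in% names(label_map)
    events <- events[keep, , drop = FALSE]
    cls <- as.integer(label_map[events$label])
  } else {
    cls <- suppressWarnings(as.integer(events$label))
    if (anyNA(cls)) stop("non-integer event labels; provide label_map")
  }
  n_epoch <- as.integer(round(edf$fs * duration))
  starts <- as.integer(round(events$onset * edf$fs)) + 1L
  ok <- starts + n_epoch - 1L <= ncol(edf$signals)
  if (!all(ok)) stop(sum(!ok), " event(s) extend past the recording end")
  data <- array(0, dim = c(length(starts), nrow(edf$signals), n_epoch))
  for (i in seq_along(starts))
    data[i, , ] <- edf$signals[, starts[i]:(starts[i] + n_epoch - 1L)]
  make_epochs(data, edf$fs, cls, rep(as.integer(session), length(starts)),
              make_montage(edf$labels))
}
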