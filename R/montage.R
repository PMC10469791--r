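#' Electrode montage with hemispheric partition
#'
#' A montage records the channel labels of an epoch set together with a
#' partition of the channel indices into left-hemisphere, right-hemisphere and
#' midline sets. The partition follows the 10-20 naming convention: labels
#' ending in `z` lie on the midline, odd electrode numbers lie over the left
#' hemisphere and even numbers over the right. Left and right index vectors are
#' aligned so that `left_idx[i]` and `right_idx[i]` are homologous mirror-pair
#' electrodes (C3 pairs with C4, FC1 with FC2, ...), which is what the
#' hemisphere-difference spatial path subtracts.
#'
#' @param channel_names character vector of electrode labels (e.g. `"C3"`,
#'   `"CPz"`). Labels must be unique.
#' @return An object of class `lgct_montage` with fields `channel_names`,
#'   `left_idx`, `right_idx`, `midline_idx` (integer indices into
#'   `channel_names`).
#' @examples
#' m <- make_montage(c("C3", "C4", "Cz"))
#' m$left_idx   # 1 (C3)
#' m$right_idx  # 2 (C4)
#' @export
make_montage <- function(channel_names) {
  stopifnot(is.character(channel_names), length(channel_names) >= 1L)
  if (anyDuplicated(channel_names)) {
    stop("duplicate channel labels: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  }
  parsed <- parse_channel_label(channel_names)
  midline_idx <- which(parsed$midline)
  left_all <- which(!parsed$midline & parsed$number %% 2L == 1L)
  right_all <- which(!parsed$midline & parsed$number %% 2L == 0L)

  # align mirror pairs: odd n pairs with n+1, even n with n-1, same prefix
  key <- function(i) paste0(parsed$prefix[i], parsed$pair_number[i])
  lk <- vapply(left_all, key, character(1))
  rk <- vapply(right_all, key, character(1))
  if (!setequal(lk, rk) || length(lk) != length(rk)) {
    miss <- c(setdiff(lk, rk), setdiff(rk, lk))
    stop("unpaired hemispheric electrodes (no mirror partner): ",
         paste(miss, collapse = ", "))
  }
  ord <- order(lk)
  left_idx <- left_all[ord]
  right_idx <- right_all[match(lk[ord], rk)]

  structure(
    list(channel_names = channel_names,
         left_idx = as.integer(left_idx),
         right_idx = as.integer(right_idx),
         midline_idx = as.integer(midline_idx)),
    class = "lgct_montage"
  )
}

# split a 10-20 label into letter prefix + electrode number (or midline flag);
# pair_number is the canonical pair id (1,2)->1, (3,4)->3, (5,6)->5, ...
parse_channel_label <- function(labels) {
  prefix <- sub("([0-9]+|z)$", "", labels)
  suffix <- substring(labels, nchar(prefix) + 1L)
  midline <- suffix == "z"
  bad <- !midline & !grepl("^[0-9]+$", suffix)
  if (any(bad)) {
    stop("cannot parse channel label(s): ", paste(labels[bad], collapse = ", "),
         " (expected 10-20 style, e.g. C3, Cz, FC6)")
  }
  number <- ifelse(midline, NA_integer_, suppressWarnings(as.integer(suffix)))
  pair_number <- ifelse(!is.na(number) & number %% 2L == 0L, number - 1L, number)
  list(prefix = prefix, number = number, midline = midline,
       pair_number = pair_number)
}

#' @export
print.lgct_montage <- function(x, ...) {
  cat("<lgct_montage> ", length(x$channel_names), " channels: ",
      length(x$left_idx), " left / ", length(x$right_idx), " right / ",
      length(x$midline_idx), " midline\n", sep = "")
  invisible(x)
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "lgct_montage"))
  n <- length(m$channel_names)
  all_idx <- c(m$left_idx, m$right_idx, m$midline_idx)
  if (length(all_idx) != n || anyDuplicated(all_idx) || !setequal(all_idx, seq_len(n)))
    stop("montage partition must cover all channels exactly once")
  if (length(m$left_idx) != length(m$right_idx))
    stop("montage has ", length(m$left_idx), " left but ",
         length(m$right_idx), " right channels")
  invisible(m)
}

#' Standard 20-channel motor-cortex montage
#'
#' The 20 motor-region electrodes used for the Korea University recordings:
#' Cz/C1-C6, CPz/CP1-CP6, FC1-FC6. Under the mirror-pair rule this partitions
#' into 9 left, 9 right and 2 midline (Cz, CPz) channels.
#'
#' @return An `lgct_montage`.
#' @export
ku_motor_montage <- function() {
  make_montage(c(
    "Cz", "C1", "C2", "C3", "C4", "C5", "C6",
    "CPz", "CP1", "CP2", "CP3", "CP4", "CP5", "CP6",
    "FC1", "FC2", "FC3", "FC4", "FC5", "FC6"
  ))
}

#' Reduced 4-channel motor montage
#'
#' A hand-area subset (C3, C4, CP3, CP4; two mirror pairs, no midline)
#' covering the electrodes where mu/beta desynchronization is strongest. Used
#' by the desk-scale example pipeline and the package's fast evaluation runs.
#'
#' @return An `lgct_montage`.
#' @export
reduced_motor_montage <- function() {
  make_montage(c("C3", "C4", "CP3", "CP4"))
}
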