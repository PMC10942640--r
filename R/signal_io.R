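#' @name edf_io
#' @title EDF read/write for EEG recordings
#'
#' @description
#' Minimal European Data Format (EDF) support: fixed-width ASCII header,
#' one data record per second, 16-bit little-endian samples mapped linearly
#' between the declared digital and physical ranges. The default physical
#' range of +/-2000 uV gives headroom over the 400 uV screening threshold
#' and typical seizure amplitudes, with a quantization step of about
#' 0.06 uV. EDF+ features (embedded annotations, discontinuous records) are
#' not used; event annotations travel in delimited sidecar files (see
#' [write_annotations()]).
NULL

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x[is.na(x)] <- "X"
  x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' @param rec an `eeg_recording`; the sample count must be a whole number of
#'   seconds and all values must lie within `phys_range`.
#' @param path output file path.
#' @param phys_range symmetric physical range in uV declared in the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 2000) {
  stopifnot_recording(rec)
  if (anyNA(rec$samples) || any(!is.finite(rec$samples)))
    stop("data error: recording contains NaN or non-finite samples")
  if (any(abs(rec$samples) > phys_range))
    stop("data error: samples exceed the declared physical range of +/-",
         phys_range, " uV")
  fs <- rec$fs
  if (fs != round(fs)) stop("data error: EDF writer requires an integer sampling rate")
  n <- nrow(rec$samples)
  if (n %% fs != 0)
    stop("data error: recording length must be a whole number of seconds")
  n_rec <- n %/% fs
  ns <- ncol(rec$samples)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii(rec$animal_id, 80),
    pad_ascii(paste(rec$group_label, rec$session_id), 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (1 + ns), 8),
    pad_ascii("", 44),
    pad_ascii(n_rec, 8),
    pad_ascii(1, 8),
    pad_ascii(ns, 4),
    paste0(pad_ascii(rec$channel_labels, 16), collapse = ""),
    paste0(pad_ascii(rep("", ns), 80), collapse = ""),
    paste0(pad_ascii(rep("uV", ns), 8), collapse = ""),
    paste0(pad_ascii(rep(-phys_range, ns), 8), collapse = ""),
    paste0(pad_ascii(rep(phys_range, ns), 8), collapse = ""),
    paste0(pad_ascii(rep(-32768L, ns), 8), collapse = ""),
    paste0(pad_ascii(rep(32767L, ns), 8), collapse = ""),
    paste0(pad_ascii(rep("", ns), 80), collapse = ""),
    paste0(pad_ascii(rep(fs, ns), 8), collapse = ""),
    paste0(pad_ascii(rep("", ns), 32), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)

  gain <- (2 * phys_range) / (32767 - (-32768))
  dig <- round((rec$samples - (-phys_range)) / gain) + (-32768)
  dig <- pmin(pmax(dig, -32768), 32767)
  # interleave: per record, all samples of signal 1, then signal 2, ...
  arr <- array(dig, dim = c(fs, n_rec, ns))
  out <- aperm(arr, c(1, 3, 2))
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

read_header_field <- function(raw, at, width, numeric = FALSE, what = "field") {
  if (at + width - 1 > length(raw))
    stop("format error: truncated EDF header at byte ", at)
  s <- trimws(rawToChar(raw[at:(at + width - 1)]))
  if (numeric) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("format error: non-numeric EDF header ", what, " at byte ", at)
    v
  } else s
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @return an `eeg_recording` with samples scaled to physical units (uV).
#'   All signals must share one sampling rate.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 256) stop("format error: EDF header shorter than 256 bytes at byte 0")
  if (read_header_field(raw, 1, 8) != "0")
    stop("format error: unsupported EDF version field at byte 0")
  patient <- read_header_field(raw, 9, 80)
  rec_field <- read_header_field(raw, 89, 80)
  n_rec <- read_header_field(raw, 237, 8, numeric = TRUE, what = "record count")
  rec_dur <- read_header_field(raw, 245, 8, numeric = TRUE, what = "record duration")
  ns <- read_header_field(raw, 253, 4, numeric = TRUE, what = "signal count")
  if (ns < 1) stop("format error: no signals declared at byte 252")
  hlen <- 256 + 256 * ns
  if (length(raw) < hlen) stop("format error: truncated signal headers at byte ", length(raw))
  fld <- function(block_offset, width, i, numeric = FALSE, what = "field") {
    at <- 256 + block_offset * ns + (i - 1) * width + 1
    read_header_field(raw, at, width, numeric, what)
  }
  labels <- vapply(seq_len(ns), function(i) fld(0, 16, i), character(1))
  pmin_ <- vapply(seq_len(ns), function(i) fld(104, 8, i, TRUE, "phys min"), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) fld(112, 8, i, TRUE, "phys max"), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) fld(120, 8, i, TRUE, "dig min"), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) fld(128, 8, i, TRUE, "dig max"), numeric(1))
  spr <- vapply(seq_len(ns), function(i) fld(216, 8, i, TRUE, "samples/record"), numeric(1))
  if (length(unique(spr)) != 1)
    stop("format error: signals with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  need <- hlen + 2 * n_rec * sum(spr)
  if (length(raw) < need)
    stop("format error: data section truncated at byte ", length(raw))
  dig <- readBin(raw[(hlen + 1):need], "integer", n = n_rec * sum(spr),
                 size = 2, signed = TRUE, endian = "little")
  arr <- array(dig, dim = c(spr[1], ns, n_rec))
  samples <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (i in seq_len(ns)) {
    samples[, i] <- as.vector(arr[, i, ]) * gain[i] + (pmin_[i] - dmin_[i] * gain[i])
  }
  recording(samples, fs, channel_labels = labels, animal_id = patient,
            session_id = rec_field)
}

#' Write event annotations to a delimited text file
#'
#' One event per row: `event_type,start_s,end_s,channel_scope,source`.
#' Times are written with full double precision so a read round trip is
#' exact. An empty table produces a header-only file.
#'
#' @param events annotation data.frame (see [annotations()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  validate_annotations(events)
  out <- events[, ANNOTATION_COLS, drop = FALSE]
  out$start_s <- sprintf("%.17g", out$start_s)
  out$end_s <- sprintf("%.17g", out$end_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read event annotations from a delimited text file
#'
#' @param path CSV path written by [write_annotations()] (or hand-made with
#'   the same columns).
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(start_s = "numeric", end_s = "numeric"))
  if (nrow(df) == 0) {
    validate_annotations(df)
    return(df)
  }
  df$channel_scope <- as.character(df$channel_scope)
  validate_annotations(df)
  df
}
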