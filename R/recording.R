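#' Construct an EEG recording
#'
#' A recording holds a multi-channel block of EEG samples in microvolts at a
#' fixed sampling rate, together with animal/group metadata. Channels are
#' columns of the sample matrix; epidural rodent EEG headmounts in this
#' pipeline carry three channels sampled at 256 Hz, but any positive channel
#' count and rate are accepted.
#'
#' @param samples numeric matrix, one column per channel, values in uV.
#'   A plain vector is treated as a single channel.
#' @param fs sampling rate in samples/second.
#' @param channel_labels character vector, one label per channel.
#' @param animal_id,group_label,session_id metadata strings.
#' @param start_offset_s seconds between session start and first sample.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(samples, fs, channel_labels = NULL,
                      animal_id = NA_character_, group_label = NA_character_,
                      session_id = NA_character_, start_offset_s = 0) {
  if (is.vector(samples) && is.numeric(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix (rows = samples, cols = channels)")
  if (ncol(samples) < 1L || nrow(samples) < 1L)
    stop("recording must contain at least one channel and one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- paste0("EEG", seq_len(ncol(samples)))
  if (length(channel_labels) != ncol(samples))
    stop("channel_labels length must equal the number of channels")
  structure(list(
    samples = samples, fs = fs, channel_labels = as.character(channel_labels),
    animal_id = animal_id, group_label = group_label,
    session_id = session_id, start_offset_s = start_offset_s
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, rec_duration_s(x)))
  cat(sprintf("  animal: %s  group: %s\n", x$animal_id, x$group_label))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
rec_duration_s <- function(rec) nrow(rec$samples) / rec$fs

n_channels <- function(rec) ncol(rec$samples)

stopifnot_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stop("expected an eeg_recording object")
  invisible(rec)
}

ANNOTATION_COLS <- c("event_type", "start_s", "end_s", "channel_scope", "source")
EVENT_TYPES <- c("GS", "SWD", "artifact", "suppression")
ANNOT_SOURCES <- c("truth", "detected", "manual")

#' Create an event annotation table
#'
#' Events are half-open intervals `[start_s, end_s)` in seconds from the
#' start of the recording. `channel_scope` is `"all"` or a channel index.
#'
#' @param event_type one of `"GS"`, `"SWD"`, `"artifact"`, `"suppression"`.
#' @param start_s,end_s interval bounds in seconds, `end_s > start_s >= 0`.
#' @param channel_scope `"all"` or a channel index (stored as character).
#' @param source one of `"truth"`, `"detected"`, `"manual"`.
#' @param ... extra per-event columns (e.g. synthesis parameters).
#' @return data.frame with one row per event.
#' @export
annotations <- function(event_type = character(), start_s = numeric(),
                        end_s = numeric(), channel_scope = "all",
                        source = "truth", ...) {
  n <- length(start_s)
  df <- data.frame(
    event_type = rep_len(as.character(event_type), n),
    start_s = as.numeric(start_s), end_s = as.numeric(end_s),
    channel_scope = rep_len(as.character(channel_scope), max(n, 0L)),
    source = rep_len(as.character(source), max(n, 0L)),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  if (n > 0) validate_annotations(df)
  df
}

#' Validate an annotation table
#'
#' Checks column presence, interval validity and event types; warns on
#' overlapping truth events of the same type.
#'
#' @param events annotation data.frame.
#' @return the (invisibly) validated table.
#' @export
validate_annotations <- function(events) {
  miss <- setdiff(ANNOTATION_COLS, names(events))
  if (length(miss)) stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(events) == 0) return(invisible(events))
  if (any(!events$event_type %in% EVENT_TYPES))
    stop("unknown event_type; expected one of ", paste(EVENT_TYPES, collapse = ", "))
  if (any(!events$source %in% ANNOT_SOURCES))
    stop("unknown source; expected one of ", paste(ANNOT_SOURCES, collapse = ", "))
  if (any(!is.finite(events$start_s)) || any(!is.finite(events$end_s)))
    stop("annotation times must be finite")
  if (any(events$start_s < 0)) stop("annotation start_s must be >= 0")
  if (any(events$end_s <= events$start_s)) stop("annotation end_s must exceed start_s")
  for (ty in unique(events$event_type[events$source == "truth"])) {
    ev <- events[events$event_type == ty & events$source == "truth", , drop = FALSE]
    if (nrow(ev) > 1) {
      ev <- ev[order(ev$start_s), ]
      if (any(ev$start_s[-1] < ev$end_s[-nrow(ev)]))
        warning("overlapping truth events of type ", ty)
    }
  }
  invisible(events)
}

empty_annotations <- function() {
  annotations(character(), numeric(), numeric())
}

#' Combine annotation tables on their common columns
#'
#' Extra per-event columns (e.g. synthesis parameters in truth tables) are
#' dropped so tables from different sources can be stacked.
#'
#' @param ... annotation data.frames (NULLs ignored).
#' @return combined annotation table sorted by onset.
#' @export
bind_events <- function(...) {
  xs <- Filter(function(x) !is.null(x), list(...))
  if (!length(xs)) return(empty_annotations())
  out <- do.call(rbind, lapply(xs, function(x) x[, ANNOTATION_COLS, drop = FALSE]))
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE for each [s1, e1) interval that intersects any [s2, e2) interval.
overlaps_any <- function(start, end, ref_start, ref_end) {
  if (length(ref_start) == 0) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i)
    any(start[i] < ref_end & end[i] > ref_start), logical(1))
}

# Union of possibly-overlapping intervals, returned sorted.
merge_intervals <- function(start, end, gap = 0) {
  if (length(start) == 0) return(data.frame(start_s = numeric(), end_s = numeric()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + gap) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start_s = c(out_s, ms), end_s = c(out_e, me))
}
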