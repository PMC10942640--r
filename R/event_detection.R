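#' Detector parameters
#'
#' Thresholds for candidate-seizure flagging, SWD detection, and GS boundary
#' refinement. The amplitude screen flags 10 s epochs in which the signal
#' exceeds 400 uV at two time points at least 1 s apart; SWD trains are
#' 5-7 Hz spike runs lasting at least 3 s; GS events longer than 45 s are
#' counted as "long".
#'
#' @param amp_threshold_uv absolute amplitude threshold, uV.
#' @param flag_epoch_s screening epoch length, seconds.
#' @param min_trigger_sep_s minimum separation of the two threshold
#'   crossings, seconds.
#' @param swd_freq_hz SWD frequency band (Hz); spikes are chained when their
#'   intervals match this band's period range within `swd_isi_tol`.
#' @param swd_min_dur_s minimum SWD train duration, seconds (>= 3).
#' @param swd_spike_z robust z-score (|x - median| / MAD) for spike picking.
#' @param swd_isi_tol fractional tolerance on the inter-spike-interval band.
#' @param swd_max_gap_complexes missing complexes tolerated inside a train.
#' @param suppression_window_s minimum duration of a low-amplitude run, s.
#' @param suppression_rms_frac fraction of the session median RMS below
#'   which a window counts as suppressed.
#' @param gs_merge_gap_s GS intervals closer than this are merged, seconds.
#' @param gs_min_dur_s GS intervals shorter than this are discarded, seconds.
#' @param gs_length_threshold_s length classifying a GS as "long", seconds.
#' @return a validated list of class `eeg_detparams`.
#' @export
detector_params <- function(amp_threshold_uv = 400, flag_epoch_s = 10,
                            min_trigger_sep_s = 1,
                            swd_freq_hz = c(5, 7), swd_min_dur_s = 3,
                            swd_spike_z = 4, swd_isi_tol = 0.1,
                            swd_max_gap_complexes = 1,
                            suppression_window_s = 30,
                            suppression_rms_frac = 0.25,
                            gs_merge_gap_s = 5, gs_min_dur_s = 10,
                            gs_length_threshold_s = 45) {
  p <- list(amp_threshold_uv = amp_threshold_uv, flag_epoch_s = flag_epoch_s,
            min_trigger_sep_s = min_trigger_sep_s, swd_freq_hz = swd_freq_hz,
            swd_min_dur_s = swd_min_dur_s, swd_spike_z = swd_spike_z,
            swd_isi_tol = swd_isi_tol,
            swd_max_gap_complexes = swd_max_gap_complexes,
            suppression_window_s = suppression_window_s,
            suppression_rms_frac = suppression_rms_frac,
            gs_merge_gap_s = gs_merge_gap_s, gs_min_dur_s = gs_min_dur_s,
            gs_length_threshold_s = gs_length_threshold_s)
  scalars <- setdiff(names(p), "swd_freq_hz")
  for (nm in scalars)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop("detector parameter ", nm, " must be a positive scalar")
  if (p$swd_min_dur_s < 3) stop("swd_min_dur_s must be at least 3 s")
  if (length(p$swd_freq_hz) != 2 || p$swd_freq_hz[1] <= 0 ||
      p$swd_freq_hz[1] >= p$swd_freq_hz[2])
    stop("swd_freq_hz must be an increasing positive range")
  class(p) <- "eeg_detparams"
  p
}

#' Flag high-amplitude screening epochs
#'
#' Tiles each channel into contiguous non-overlapping epochs of
#' `flag_epoch_s` seconds and flags an epoch when the absolute signal
#' exceeds `amp_threshold_uv` at two time points at least `min_trigger_sep_s`
#' apart within the epoch. A trailing partial epoch is not screened.
#'
#' @param rec an `eeg_recording`, at least one epoch long.
#' @param params an `eeg_detparams`.
#' @return data.frame of flags sorted by `start_s`: `start_s`, `dur_s`,
#'   `reason`, `channel`, `n_triggers`, `first_trigger_s`, `last_trigger_s`.
#' @export
flag_high_amplitude_epochs <- function(rec, params = detector_params()) {
  stopifnot_recording(rec)
  fs <- rec$fs
  ep_n <- round(params$flag_epoch_s * fs)
  if (nrow(rec$samples) < ep_n)
    stop("recording shorter than one screening epoch")
  out <- list()
  for (ch in seq_len(n_channels(rec))) {
    x <- rec$samples[, ch]
    hit <- which(abs(x) > params$amp_threshold_uv)
    if (length(hit) < 2) next
    ep <- (hit - 1L) %/% ep_n
    for (e in unique(ep)) {
      h <- hit[ep == e]
      t <- (h - 1) / fs
      if (length(h) >= 2 && (max(t) - min(t)) >= params$min_trigger_sep_s) {
        out[[length(out) + 1]] <- data.frame(
          start_s = e * params$flag_epoch_s, dur_s = params$flag_epoch_s,
          reason = "high_amplitude", channel = ch, n_triggers = length(h),
          first_trigger_s = min(t), last_trigger_s = max(t))
      }
    }
  }
  if (!length(out))
    return(data.frame(start_s = numeric(), dur_s = numeric(),
                      reason = character(), channel = integer(),
                      n_triggers = integer(), first_trigger_s = numeric(),
                      last_trigger_s = numeric()))
  res <- do.call(rbind, out)
  res[order(res$start_s, res$channel), ]
}

# Per-window RMS of the channel-mean RMS, over non-overlapping 1 s windows.
windowed_rms <- function(rec, win_s = 1) {
  fs <- rec$fs
  wn <- round(win_s * fs)
  n_win <- nrow(rec$samples) %/% wn
  if (n_win < 1) stop("recording shorter than one RMS window")
  per_ch <- vapply(seq_len(n_channels(rec)), function(ch) {
    x2 <- rec$samples[seq_len(n_win * wn), ch]^2
    sqrt(colMeans(matrix(x2, nrow = wn)))
  }, numeric(n_win))
  rowMeans(as.matrix(per_ch))
}

#' Flag persistent low-amplitude (suppression-like) runs
#'
#' Computes RMS amplitude in 1 s windows (averaged across channels), then
#' flags maximal runs in which the RMS stays below `suppression_rms_frac`
#' times the session median RMS for at least `suppression_window_s`. The
#' threshold is relative: a uniformly low-amplitude recording produces no
#' flags.
#'
#' @inheritParams flag_high_amplitude_epochs
#' @return data.frame of flags: `start_s`, `dur_s`, `reason`, `channel`
#'   (NA: channel-averaged), `n_triggers`, `first_trigger_s`,
#'   `last_trigger_s`.
#' @export
flag_low_amplitude_epochs <- function(rec, params = detector_params()) {
  stopifnot_recording(rec)
  if (rec_duration_s(rec) < 600)
    stop("session must be at least 10 min to estimate the median RMS")
  w <- windowed_rms(rec, 1)
  med <- stats::median(w)
  below <- w < params$suppression_rms_frac * med
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= params$suppression_window_s
  if (!any(keep))
    return(data.frame(start_s = numeric(), dur_s = numeric(),
                      reason = character(), channel = integer(),
                      n_triggers = integer(), first_trigger_s = numeric(),
                      last_trigger_s = numeric()))
  data.frame(start_s = starts[keep] - 1, dur_s = r$lengths[keep],
             reason = "low_amplitude", channel = NA_integer_,
             n_triggers = r$lengths[keep],
             first_trigger_s = starts[keep] - 1, last_trigger_s = ends[keep] - 1)
}

# Local maxima of |x - median| above a robust z threshold. The refractory
# (default: the shortest in-band complex period) keeps only the largest
# extremum of any closer pair, so wave components of a complex are not
# double-counted as spikes.
pick_spikes <- function(x, fs, z_thresh, refractory_s = 0.1) {
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) return(numeric(0))
  a <- abs(x - med)
  n <- length(a)
  if (n < 3) return(numeric(0))
  loc <- which(a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] > a[3:n]) + 1L
  loc <- loc[a[loc] / s > z_thresh]
  if (!length(loc)) return(numeric(0))
  o <- loc[order(a[loc], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  ref_n <- round(refractory_s * fs)
  for (i in o) {
    if (!length(kept) || all(abs(kept - i) >= ref_n)) kept <- c(kept, i)
  }
  sort(kept - 1) / fs
}

# Chain spike times into runs whose inter-spike intervals fit the SWD band,
# allowing up to `max_gap` single missing complexes per run.
chain_spikes <- function(times, isi_lo, isi_hi, max_gap) {
  if (length(times) < 2) return(list())
  runs <- list()
  cur <- times[1]
  gaps <- 0
  for (i in 2:length(times)) {
    isi <- times[i] - times[i - 1]
    if (isi >= isi_lo && isi <= isi_hi) {
      cur <- c(cur, times[i])
    } else if (isi > isi_hi && isi <= 2 * isi_hi && gaps < max_gap) {
      cur <- c(cur, times[i]); gaps <- gaps + 1
    } else {
      runs[[length(runs) + 1]] <- cur
      cur <- times[i]; gaps <- 0
    }
  }
  runs[[length(runs) + 1]] <- cur
  runs
}

#' Detect spike-and-wave discharge trains
#'
#' Per channel: (1) pick spikes as local extrema whose robust z-score
#' (|x - median| / MAD) exceeds `swd_spike_z`; (2) chain spikes whose
#' intervals lie in the period band of `swd_freq_hz` widened by
#' `swd_isi_tol`, allowing up to `swd_max_gap_complexes` missing complexes;
#' (3) keep runs spanning at least `swd_min_dur_s` with at least
#' `ceiling(5 * swd_min_dur_s)` spikes; (4) merge events that overlap across
#' channels; (5) drop events overlapping intervals in `exclude` (detected GS
#' or labeled artifacts).
#'
#' @inheritParams flag_high_amplitude_epochs
#' @param exclude annotation table of GS/artifact intervals to exclude.
#' @return sorted, non-overlapping annotation table with
#'   `event_type = "SWD"`, `source = "detected"`.
#' @export
detect_swd <- function(rec, params = detector_params(), exclude = NULL) {
  stopifnot_recording(rec)
  isi_lo <- (1 / params$swd_freq_hz[2]) * (1 - params$swd_isi_tol)
  isi_hi <- (1 / params$swd_freq_hz[1]) * (1 + params$swd_isi_tol)
  min_spikes <- ceiling(5 * params$swd_min_dur_s)
  ev_s <- numeric(0); ev_e <- numeric(0)
  for (ch in seq_len(n_channels(rec))) {
    times <- pick_spikes(rec$samples[, ch], rec$fs, params$swd_spike_z,
                         refractory_s = isi_lo)
    for (run in chain_spikes(times, isi_lo, isi_hi, params$swd_max_gap_complexes)) {
      if (length(run) < 2) next
      # the train spans from the start of the first complex to the end of
      # the last: spike-peak span plus one inter-spike interval
      half <- stats::median(diff(run)) / 2
      span <- (run[length(run)] - run[1]) + 2 * half
      if (span >= params$swd_min_dur_s && length(run) >= min_spikes) {
        ev_s <- c(ev_s, max(0, run[1] - half))
        ev_e <- c(ev_e, min(rec_duration_s(rec), run[length(run)] + half))
      }
    }
  }
  merged <- merge_intervals(ev_s, ev_e)
  if (nrow(merged) && !is.null(exclude) && nrow(exclude)) {
    drop <- overlaps_any(merged$start_s, merged$end_s,
                         exclude$start_s, exclude$end_s)
    merged <- merged[!drop, , drop = FALSE]
  }
  annotations(rep("SWD", nrow(merged)), merged$start_s, merged$end_s,
              source = "detected")
}

# Channel-mean line length in non-overlapping 1 s windows.
windowed_line_length <- function(rec, win_s = 1) {
  fs <- rec$fs
  wn <- round(win_s * fs)
  n_win <- nrow(rec$samples) %/% wn
  per_ch <- vapply(seq_len(n_channels(rec)), function(ch) {
    d <- abs(diff(rec$samples[seq_len(n_win * wn), ch]))
    d <- c(d, 0)  # align to windows; last diff of each window belongs to it
    colSums(matrix(d, nrow = wn))
  }, numeric(n_win))
  rowMeans(as.matrix(per_ch))
}

#' Refine high-amplitude flags into GS annotations
#'
#' Automated surrogate for manual seizure marking: each flagged epoch is
#' expanded to the maximal surrounding run of 1 s windows whose channel-mean
#' line length exceeds 3x the session median; intervals separated by less
#' than `gs_merge_gap_s` are merged; intervals shorter than `gs_min_dur_s`
#' or overlapping `exclude` (labeled artifacts) are discarded.
#'
#' @inheritParams detect_swd
#' @param flags output of [flag_high_amplitude_epochs()].
#' @return annotation table with `event_type = "GS"`, `source = "detected"`.
#' @export
review_flags_to_gs <- function(rec, flags, params = detector_params(),
                               exclude = NULL) {
  stopifnot_recording(rec)
  if (is.null(flags) || nrow(flags) == 0)
    return(empty_annotations())
  llw <- windowed_line_length(rec, 1)
  thr <- 3 * stats::median(llw)
  active <- llw > thr
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run_s <- (starts[r$values] - 1)
  run_e <- ends[r$values]
  if (!length(run_s)) return(empty_annotations())
  keep <- overlaps_any(run_s, run_e, flags$start_s, flags$start_s + flags$dur_s)
  run_s <- run_s[keep]; run_e <- run_e[keep]
  if (!length(run_s)) return(empty_annotations())
  merged <- merge_intervals(run_s, run_e, gap = params$gs_merge_gap_s)
  len_ok <- (merged$end_s - merged$start_s) >= params$gs_min_dur_s
  merged <- merged[len_ok, , drop = FALSE]
  if (nrow(merged) && !is.null(exclude) && nrow(exclude)) {
    drop <- overlaps_any(merged$start_s, merged$end_s,
                         exclude$start_s, exclude$end_s)
    merged <- merged[!drop, , drop = FALSE]
  }
  annotations(rep("GS", nrow(merged)), merged$start_s, merged$end_s,
              source = "detected")
}

#' Classify GS events by length
#'
#' Counts events whose duration exceeds `threshold_s` (default 45 s).
#'
#' @param events GS annotation table, or a numeric vector of durations (s).
#' @param threshold_s length threshold in seconds.
#' @return list with `n_long`, `n_total`, `fraction` (0 when no events).
#' @export
classify_gs_lengths <- function(events, threshold_s = 45) {
  durs <- if (is.data.frame(events)) {
    if (nrow(events) && any(events$event_type != "GS"))
      stop("classify_gs_lengths expects GS events only")
    events$end_s - events$start_s
  } else as.numeric(events)
  n_long <- sum(durs > threshold_s)
  n_total <- length(durs)
  list(n_long = n_long, n_total = n_total,
       fraction = if (n_total > 0) n_long / n_total else 0)
}

# Sampled 1 h epoch starts (seconds): eight evenly spaced epochs per 24 h
# session, two sessions. Falls back to the same 1-in-3-hours density when
# the recording is shorter than two full sessions.
swd_sampling_epochs <- function(rec_hours) {
  if (rec_hours >= 48) {
    starts <- as.vector(outer(0:7 * 3, c(0, 24), "+"))
    list(starts_h = starts, hours = 16, fallback = FALSE)
  } else {
    n_ep <- max(1, floor(rec_hours / 3))
    spacing <- rec_hours / n_ep
    starts <- (0:(n_ep - 1)) * spacing
    starts <- starts[starts + 1 <= rec_hours]
    if (!length(starts)) starts <- 0
    list(starts_h = starts, hours = length(starts), fallback = TRUE)
  }
}

#' Summarize per-animal event rates
#'
#' GS rate is events per day of recording; SWD rate is events per hour,
#' either from the full scan (`swd_sampling = "full"`) or from eight evenly
#' spaced 1 h epochs in each of two 24 h sessions (`"subsampled"`, the
#' review scheme; an SWD is counted when its onset falls in a sampled hour).
#' Recordings shorter than 48 h fall back, with a warning, to proportional
#' subsampling at the same 1-hour-in-3 density.
#'
#' @param events annotation table (GS and SWD events; other types ignored).
#' @param rec_hours recorded hours, > 0.
#' @param swd_sampling `"full"` or `"subsampled"`.
#' @param animal_id,group_label metadata carried into the summary.
#' @param gs_length_threshold_s threshold for the long-GS fraction.
#' @return one-row data.frame (animal summary): ids, `total_hours`,
#'   `gs_count`, `gs_positive`, `gs_rate_per_day`, `mean_gs_length_s`,
#'   `long_gs_fraction`, `swd_count`, `swd_rate_per_hour`,
#'   `mean_swd_length_s`.
#' @export
compute_event_rates <- function(events, rec_hours,
                                swd_sampling = c("full", "subsampled"),
                                animal_id = NA_character_,
                                group_label = NA_character_,
                                gs_length_threshold_s = 45) {
  swd_sampling <- match.arg(swd_sampling)
  if (!is.numeric(rec_hours) || rec_hours <= 0) stop("rec_hours must be > 0")
  gs <- events[events$event_type == "GS", , drop = FALSE]
  swd <- events[events$event_type == "SWD", , drop = FALSE]
  if (swd_sampling == "full") {
    swd_count <- nrow(swd)
    swd_rate <- swd_count / rec_hours
  } else {
    plan <- swd_sampling_epochs(rec_hours)
    if (plan$fallback)
      warning("recording shorter than two 24 h sessions; ",
              "using proportional subsampling over ", plan$hours, " h")
    h <- swd$start_s / 3600
    in_epoch <- vapply(h, function(t) any(t >= plan$starts_h & t < plan$starts_h + 1),
                       logical(1))
    swd_count <- sum(in_epoch)
    swd_rate <- swd_count / plan$hours
  }
  cls <- classify_gs_lengths(gs, gs_length_threshold_s)
  data.frame(
    animal_id = animal_id, group_label = group_label, total_hours = rec_hours,
    gs_count = nrow(gs), gs_positive = nrow(gs) > 0,
    gs_rate_per_day = nrow(gs) / (rec_hours / 24),
    mean_gs_length_s = if (nrow(gs)) mean(gs$end_s - gs$start_s) else NA_real_,
    long_gs_fraction = cls$fraction,
    swd_count = swd_count, swd_rate_per_hour = swd_rate,
    mean_swd_length_s = if (nrow(swd)) mean(swd$end_s - swd$start_s) else NA_real_,
    stringsAsFactors = FALSE)
}
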