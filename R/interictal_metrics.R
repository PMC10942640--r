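#' Epoch sampling plan
#'
#' Baseline (interictal) EEG measures are computed over short epochs placed
#' evenly across a recording: by default 692 epochs of 5 s per 24 h session,
#' the same density as the screening protocol this pipeline reproduces.
#'
#' @param n_epochs number of epochs over the recording span.
#' @param epoch_dur_s epoch duration in seconds.
#' @return list of class `eeg_samplingplan`.
#' @export
sampling_plan <- function(n_epochs = 692, epoch_dur_s = 5) {
  if (n_epochs < 1 || epoch_dur_s <= 0) stop("invalid sampling plan")
  structure(list(n_epochs = n_epochs, epoch_dur_s = epoch_dur_s),
            class = "eeg_samplingplan")
}

#' Sampling plan scaled to a recording length
#'
#' Keeps the default density (692 five-second epochs per 24 h) for
#' recordings of any length, with a floor of 12 epochs.
#'
#' @param duration_s recording length in seconds.
#' @param epoch_dur_s epoch duration in seconds.
#' @return an `eeg_samplingplan`.
#' @export
scaled_sampling_plan <- function(duration_s, epoch_dur_s = 5) {
  n <- max(12L, round(692 * duration_s / 86400))
  n <- min(n, floor(duration_s / epoch_dur_s))
  sampling_plan(n_epochs = max(1L, n), epoch_dur_s = epoch_dur_s)
}

#' Sample evenly spaced analysis epochs
#'
#' Epoch i starts at `i * T / n_epochs` (i = 0..n-1) where T is the
#' recording span. Epochs overlapping any interval in `events` (detected or
#' labeled GS/SWD/artifact/suppression) are marked not retained, so
#' downstream summaries stay interictal.
#'
#' @param rec an `eeg_recording`.
#' @param plan an `eeg_samplingplan`.
#' @param events annotation table used for exclusion (optional).
#' @return data.frame with `epoch_start_s` and logical `retained`.
#' @export
sample_epochs <- function(rec, plan = sampling_plan(), events = NULL) {
  stopifnot_recording(rec)
  T_s <- rec_duration_s(rec)
  if (T_s < plan$epoch_dur_s) stop("recording shorter than one analysis epoch")
  spacing <- T_s / plan$n_epochs
  if (spacing < plan$epoch_dur_s)
    stop("sampling plan would overlap epochs (spacing ", signif(spacing, 3),
         " s < epoch duration); reduce n_epochs or use scaled_sampling_plan()")
  starts <- (seq_len(plan$n_epochs) - 1) * spacing
  starts <- starts[starts + plan$epoch_dur_s <= T_s]
  retained <- rep(TRUE, length(starts))
  if (!is.null(events) && nrow(events) > 0)
    retained <- !overlaps_any(starts, starts + plan$epoch_dur_s,
                              events$start_s, events$end_s)
  data.frame(epoch_start_s = starts, retained = retained)
}

#' Line length (coastline) of an epoch
#'
#' Sum of absolute differences between adjacent samples; the classic
#' seizure-screening feature.
#'
#' @param x numeric vector of samples (uV), length >= 2.
#' @return line length in uV.
#' @export
line_length <- function(x) {
  if (length(x) < 2) stop("line_length needs at least 2 samples")
  sum(abs(diff(x)))
}

#' Mean absolute amplitude of an epoch
#'
#' @param x numeric vector of samples (uV), non-empty.
#' @return mean of |x| in uV.
#' @export
mean_amplitude <- function(x) {
  if (length(x) < 1) stop("mean_amplitude needs at least 1 sample")
  mean(abs(x))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with the segmentation convention of the
#' MATLAB `pwelch` default: the signal is split into `n_segments` segments
#' with 50% overlap, each windowed (Hamming by default), and the one-sided
#' density is averaged over segments. Units are uV^2/Hz; the integral of
#' the density recovers the signal mean square (discrete Parseval).
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate, Hz.
#' @param n_segments nominal number of 50%-overlapping segments.
#' @param window `"hamming"`, `"hann"`, or `"rectangular"`.
#' @return data.frame with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, n_segments = 8, window = "hamming") {
  n <- length(x)
  L <- floor(2 * n / (n_segments + 1))
  if (L < 8) stop("too few samples for a Welch segment")
  step <- floor(L / 2)
  w <- switch(window,
              hamming = signal::hamming(L),
              hann = signal::hanning(L),
              rectangular = rep(1, L),
              stop("unknown window: ", window))
  starts <- seq(1, n - L + 1, by = step)
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    p <- Mod(stats::fft(seg))^2 / scale
    ps <- p[seq_len(nf)]
    ps[2:(nf - 1)] <- 2 * ps[2:(nf - 1)]
    if (L %% 2 == 1) ps[nf] <- 2 * ps[nf]
    acc <- acc + ps
  }
  data.frame(freq = (seq_len(nf) - 1) * fs / L, psd = acc / length(starts))
}

#' Integrate a PSD into 1 Hz band powers (bands 1-30)
#'
#' Band k integrates the density over the half-open bin
#' `[k - 0.5, k + 0.5)` Hz; total power is the sum over bands 1-30 and
#' relative power is each band divided by the total.
#'
#' @param psd data.frame from [welch_psd()]; must cover at least 30.5 Hz
#'   with frequency resolution no coarser than 1 Hz.
#' @return list with `band_power` (named 30-vector, uV^2), `total_power_uv2`
#'   and `relative_power` (sums to 1).
#' @export
band_powers <- function(psd) {
  df <- diff(psd$freq[1:2])
  if (max(psd$freq) < 30.5)
    stop("PSD must cover at least 30.5 Hz")
  if (df > 1)
    stop("insufficient frequency resolution for 1 Hz bands (bin width ",
         signif(df, 3), " Hz)")
  bands <- vapply(1:30, function(k)
    sum(psd$psd[psd$freq >= k - 0.5 & psd$freq < k + 0.5]) * df, numeric(1))
  names(bands) <- paste0("band_", 1:30)
  total <- sum(bands)
  rel <- if (total > 0) bands / total else rep(NA_real_, 30)
  list(band_power = bands, total_power_uv2 = total, relative_power = rel)
}

#' Per-animal interictal metric summary
#'
#' For every retained epoch of the sampling plan, computes line length,
#' mean absolute amplitude, total power and 1-30 Hz band powers per channel,
#' averages each metric across channels, then averages over epochs. Also
#' reports the cumulative coastline (sum over retained epochs of the
#' channel-mean line length).
#'
#' @param rec an `eeg_recording`.
#' @param plan an `eeg_samplingplan`.
#' @param events annotation table; overlapping epochs are excluded.
#' @return list with `per_epoch` (data.frame) and `animal` (list of means:
#'   `mean_line_length_uv`, `mean_amplitude_uv`, `mean_total_power_uv2`,
#'   `cumulative_coastline_uv`, `band_power`, `relative_power`,
#'   `n_epochs_retained`, `n_epochs_excluded`).
#' @export
summarize_animal_metrics <- function(rec, plan = sampling_plan(), events = NULL) {
  stopifnot_recording(rec)
  ep <- sample_epochs(rec, plan, events)
  use <- ep$epoch_start_s[ep$retained]
  if (!length(use)) stop("no retained interictal epochs")
  fs <- rec$fs
  nch <- n_channels(rec)
  ep_n <- round(plan$epoch_dur_s * fs)
  rows <- vector("list", length(use))
  band_acc <- matrix(0, nrow = length(use), ncol = 30)
  rel_acc <- matrix(0, nrow = length(use), ncol = 30)
  for (i in seq_along(use)) {
    i0 <- round(use[i] * fs) + 1L
    ll <- ma <- tp <- 0
    bp <- rp <- numeric(30)
    for (ch in seq_len(nch)) {
      seg <- rec$samples[i0:(i0 + ep_n - 1L), ch]
      ll <- ll + line_length(seg)
      ma <- ma + mean_amplitude(seg)
      pw <- band_powers(welch_psd(seg, fs))
      tp <- tp + pw$total_power_uv2
      bp <- bp + pw$band_power
      rp <- rp + pw$relative_power
    }
    rows[[i]] <- data.frame(epoch_start_s = use[i], line_length_uv = ll / nch,
                            mean_amp_uv = ma / nch, total_power_uv2 = tp / nch)
    band_acc[i, ] <- bp / nch
    rel_acc[i, ] <- rp / nch
  }
  per_epoch <- do.call(rbind, rows)
  band_mean <- colMeans(band_acc)
  rel_mean <- colMeans(rel_acc)
  names(band_mean) <- names(rel_mean) <- paste0("band_", 1:30)
  list(per_epoch = per_epoch,
       animal = list(
         mean_line_length_uv = mean(per_epoch$line_length_uv),
         mean_amplitude_uv = mean(per_epoch$mean_amp_uv),
         mean_total_power_uv2 = mean(per_epoch$total_power_uv2),
         cumulative_coastline_uv = sum(per_epoch$line_length_uv),
         band_power = band_mean, relative_power = rel_mean,
         n_epochs_retained = length(use),
         n_epochs_excluded = sum(!ep$retained)))
}
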