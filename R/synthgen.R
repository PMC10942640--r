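#' Synthetic rodent EEG generator configuration
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults follow
#' the recording conditions of the chronic video-EEG protocol this package
#' quantifies: three epidural channels at 256 Hz, 1/f-like background, rare
#' generalized seizures (GS) with postictal suppression, 5-7 Hz
#' spike-and-wave discharge (SWD) trains lasting at least 3 s, and brief
#' movement artifacts.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate, samples/second.
#' @param n_channels number of EEG channels.
#' @param baseline_rms background RMS amplitude in uV.
#' @param spectral_exponent alpha of the 1/f^alpha background spectrum.
#' @param gs_rate_per_day expected GS events per 24 h (Poisson).
#' @param gs_dur_s length-2 range of GS durations in seconds.
#' @param gs_amplitude_uv peak absolute amplitude of GS activity in uV.
#' @param suppression_factor multiplier on baseline RMS during postictal
#'   suppression (0-1).
#' @param suppression_dur_s suppression window length in seconds; the second
#'   half ramps linearly back to baseline.
#' @param swd_rate_per_hour expected SWD trains per hour (Poisson).
#' @param swd_freq_hz length-2 frequency range of SWD trains, within 5-7 Hz.
#' @param swd_dur_s length-2 range of SWD train durations, minimum >= 3 s.
#' @param swd_amplitude_uv peak absolute amplitude of the spike component, uV.
#' @param artifact_rate_per_hour expected movement artifacts per hour.
#' @param artifact_amplitude_uv peak amplitude of artifact bursts, uV.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   signals and ground truth.
#' @return a validated list of class `eeg_genconfig`.
#' @export
generator_config <- function(duration_s = 3600, fs = 256, n_channels = 3,
                             baseline_rms = 40, spectral_exponent = 2,
                             gs_rate_per_day = 0.5, gs_dur_s = c(20, 60),
                             gs_amplitude_uv = 600,
                             suppression_factor = 0.3, suppression_dur_s = 60,
                             swd_rate_per_hour = 10, swd_freq_hz = c(5, 7),
                             swd_dur_s = c(3, 8), swd_amplitude_uv = 300,
                             artifact_rate_per_hour = 2,
                             artifact_amplitude_uv = 500,
                             seed = 1L) {
  cfg <- list(duration_s = duration_s, fs = fs, n_channels = n_channels,
              baseline_rms = baseline_rms, spectral_exponent = spectral_exponent,
              gs_rate_per_day = gs_rate_per_day, gs_dur_s = gs_dur_s,
              gs_amplitude_uv = gs_amplitude_uv,
              suppression_factor = suppression_factor,
              suppression_dur_s = suppression_dur_s,
              swd_rate_per_hour = swd_rate_per_hour, swd_freq_hz = swd_freq_hz,
              swd_dur_s = swd_dur_s, swd_amplitude_uv = swd_amplitude_uv,
              artifact_rate_per_hour = artifact_rate_per_hour,
              artifact_amplitude_uv = artifact_amplitude_uv,
              seed = as.integer(seed))
  check_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("invalid generator config field: ", field, " must be a positive number")
  }
  check_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("invalid generator config field: ", field, " must be non-negative")
  }
  check_range <- function(field, lo = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) || v[1] > v[2] || v[1] < lo)
      stop("invalid generator config field: ", field, " must be an increasing length-2 range")
  }
  check_pos("duration_s"); check_pos("fs"); check_pos("n_channels")
  check_nonneg("baseline_rms"); check_nonneg("spectral_exponent")
  check_nonneg("gs_rate_per_day"); check_nonneg("swd_rate_per_hour")
  check_nonneg("artifact_rate_per_hour")
  check_pos("gs_amplitude_uv"); check_pos("swd_amplitude_uv")
  check_pos("artifact_amplitude_uv"); check_pos("suppression_dur_s")
  check_range("gs_dur_s"); check_range("swd_dur_s", lo = 3); check_range("swd_freq_hz")
  if (cfg$swd_freq_hz[1] < 5 || cfg$swd_freq_hz[2] > 7)
    stop("invalid generator config field: swd_freq_hz must lie within [5, 7]")
  if (cfg$suppression_factor < 0 || cfg$suppression_factor > 1)
    stop("invalid generator config field: suppression_factor must be in [0, 1]")
  if (!is.finite(cfg$seed)) stop("invalid generator config field: seed")
  class(cfg) <- "eeg_genconfig"
  cfg
}

# Distinct deterministic RNG streams for each synthesis stage.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 16807) %% 2147483629)
}

#' Generate 1/f-like baseline EEG
#'
#' Produces zero-mean Gaussian noise shaped in the frequency domain so the
#' power spectrum falls as 1/f^alpha above 1 Hz (flat below, to keep the
#' variance finite), then rescales each channel to exactly the configured
#' RMS. Deterministic under the config seed.
#'
#' @param config an `eeg_genconfig`.
#' @param animal_id,group_label metadata passed to the recording.
#' @return an `eeg_recording`.
#' @export
generate_baseline <- function(config, animal_id = "synthetic",
                              group_label = NA_character_) {
  if (!inherits(config, "eeg_genconfig")) stop("config must come from generator_config()")
  n <- round(config$duration_s * config$fs)
  x <- withr::with_seed(derive_seed(config$seed, 1L), {
    vapply(seq_len(config$n_channels), function(ch) {
      w <- stats::rnorm(n)
      f <- seq(0, config$fs, length.out = n + 1)[seq_len(n)]
      f <- pmin(f, config$fs - f)             # two-sided frequency axis
      h <- pmax(f, 1) ^ (-config$spectral_exponent / 2)
      h[1] <- 0                               # remove DC
      y <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
      y <- y - mean(y)
      r <- sqrt(mean(y^2))
      if (r > 0) y * (config$baseline_rms / r) else y * 0
    }, numeric(n))
  })
  recording(x, config$fs, animal_id = animal_id, group_label = group_label,
            session_id = paste0("synth-", config$seed))
}

# Poisson event placement by uniform proposal with rejection on overlap.
# `footprint` extends each event's reserved interval beyond its nominal end
# (e.g. postictal suppression). Errors out after `max_retry` failed proposals.
place_events <- function(n_events, duration_s, event_dur, footprint_after = 0,
                         avoid = NULL, margin = 1, max_retry = 1000) {
  starts <- numeric(0)
  res_s <- if (is.null(avoid) || nrow(avoid) == 0) numeric(0) else avoid$start_s - margin
  res_e <- if (is.null(avoid) || nrow(avoid) == 0) numeric(0) else avoid$end_s + margin
  for (i in seq_len(n_events)) {
    span <- event_dur[i] + footprint_after
    if (span >= duration_s) stop("event placement failed: event longer than recording")
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      s <- stats::runif(1, 0, duration_s - span)
      if (!any(s < res_e & (s + span) > res_s)) {
        starts <- c(starts, s)
        res_s <- c(res_s, s - margin); res_e <- c(res_e, s + span + margin)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("event placement failed after ", max_retry,
           " retries; requested rate too high for non-overlapping placement")
  }
  starts
}

# Spike-wave complex: one sharp positive transient per cycle riding on a
# slower negative half-wave. Harmonic-rich on purpose, so spike-picking
# detectors see realistic morphology rather than a sinusoid.
swd_waveform <- function(freq_hz, dur_s, fs, amplitude_uv) {
  n <- max(2L, round(dur_s * fs))
  t <- (seq_len(n) - 1) / fs
  ph <- (t * freq_hz) %% 1                      # cycle phase in [0, 1)
  spike <- exp(-0.5 * ((ph - 0.5) / 0.05)^2)
  spike <- spike - mean(spike)                  # AC-coupled: no DC component
  wave <- -0.3 * sin(2 * pi * t * freq_hz)
  raw <- spike + wave
  ramp_n <- max(2L, round(fs / freq_hz / 2))    # half-cycle cosine taper
  env <- rep(1, n)
  up <- seq_len(min(ramp_n, n))
  env[up] <- (1 - cos(pi * (up - 1) / ramp_n)) / 2
  env[n + 1 - up] <- pmin(env[n + 1 - up], (1 - cos(pi * (up - 1) / ramp_n)) / 2)
  raw <- raw * env
  raw * (amplitude_uv / max(abs(raw)))
}

# Generalized-seizure stand-in: polyspike activity with a slowly wandering
# instantaneous frequency (4-10 Hz) and a rise/fall amplitude envelope.
gs_waveform <- function(dur_s, fs, amplitude_uv) {
  n <- max(2L, round(dur_s * fs))
  t <- (seq_len(n) - 1) / fs
  f_inst <- 7 + 3 * sin(2 * pi * 0.07 * t + stats::runif(1, 0, 2 * pi))
  phase <- cumsum(f_inst) / fs
  ph <- phase %% 1
  spike <- exp(-0.5 * ((ph - 0.5) / 0.06)^2)
  wave <- -0.5 * sin(2 * pi * phase)
  raw <- spike + wave + 0.15 * stats::rnorm(n)
  raw <- raw - mean(raw)
  ramp <- min(2, dur_s / 4)
  env <- pmin(1, pmin(t, rev(t)) / ramp)
  raw <- raw * env
  raw * (amplitude_uv / max(abs(raw)))
}

# High-frequency (>20 Hz) burst shorter than 1 s, for movement artifacts.
artifact_waveform <- function(freq_hz, dur_s, fs, amplitude_uv) {
  n <- max(2L, round(dur_s * fs))
  t <- (seq_len(n) - 1) / fs
  env <- exp(-0.5 * ((t - dur_s / 2) / (dur_s / 5))^2)
  raw <- sin(2 * pi * freq_hz * t + stats::runif(1, 0, 2 * pi)) * env
  raw * (amplitude_uv / max(abs(raw)))
}

add_event_to_channels <- function(samples, wave, i0, gains) {
  idx <- i0 + seq_along(wave) - 1L
  keep <- idx >= 1L & idx <= nrow(samples)
  for (ch in seq_len(ncol(samples)))
    samples[idx[keep], ch] <- samples[idx[keep], ch] + wave[keep] * gains[ch]
  samples
}

#' Inject spike-and-wave discharge trains
#'
#' Adds Poisson-placed SWD trains (count ~ Poisson(rate x hours)) to all
#' channels with a per-channel gain jitter of +/-10%. Each train is a
#' periodic spike-wave complex at a frequency drawn from `swd_freq_hz` and a
#' duration drawn from `swd_dur_s` (>= 3 s). Trains never overlap each other
#' or intervals listed in `avoid`.
#'
#' @param rec an `eeg_recording`.
#' @param config an `eeg_genconfig`.
#' @param avoid annotation table of intervals that must stay event-free.
#' @return list with elements `recording` and `truth` (annotations with
#'   per-event `freq_hz` and `amp_uv` columns).
#' @export
inject_swd_trains <- function(rec, config, avoid = NULL) {
  stopifnot_recording(rec)
  dur <- rec_duration_s(rec)
  withr::with_seed(derive_seed(config$seed, 2L), {
    n_events <- stats::rpois(1, config$swd_rate_per_hour * dur / 3600)
    if (n_events == 0) {
      list(recording = rec, truth = empty_annotations())
    } else {
      durs <- stats::runif(n_events, config$swd_dur_s[1], config$swd_dur_s[2])
      freqs <- stats::runif(n_events, config$swd_freq_hz[1], config$swd_freq_hz[2])
      starts <- place_events(n_events, dur, durs, avoid = avoid)
      for (i in seq_len(n_events)) {
        wave <- swd_waveform(freqs[i], durs[i], rec$fs, config$swd_amplitude_uv)
        gains <- 1 + stats::runif(n_channels(rec), -0.1, 0.1)
        rec$samples <- add_event_to_channels(rec$samples, wave,
                                             round(starts[i] * rec$fs) + 1L, gains)
      }
      truth <- annotations("SWD", starts, starts + durs, source = "truth",
                           freq_hz = freqs, amp_uv = config$swd_amplitude_uv)
      list(recording = rec, truth = truth[order(truth$start_s), ])
    }
  })
}

#' Inject generalized seizures with postictal suppression
#'
#' Adds Poisson-placed GS events (count ~ Poisson(rate x days)): mixed-
#' frequency polyspike activity scaled to `gs_amplitude_uv` peak, followed
#' immediately by a suppression window in which the existing signal is
#' attenuated by `suppression_factor` (with a linear recovery ramp over the
#' second half of the window). The GS truth interval excludes suppression;
#' suppression windows are annotated separately.
#'
#' @inheritParams inject_swd_trains
#' @return list with `recording` and `truth`.
#' @export
inject_gs <- function(rec, config, avoid = NULL) {
  stopifnot_recording(rec)
  dur <- rec_duration_s(rec)
  withr::with_seed(derive_seed(config$seed, 3L), {
    n_events <- stats::rpois(1, config$gs_rate_per_day * dur / 86400)
    if (n_events == 0) {
      list(recording = rec, truth = empty_annotations())
    } else {
      durs <- stats::runif(n_events, config$gs_dur_s[1], config$gs_dur_s[2])
      starts <- place_events(n_events, dur, durs,
                             footprint_after = config$suppression_dur_s, avoid = avoid)
      for (i in seq_len(n_events)) {
        wave <- gs_waveform(durs[i], rec$fs, config$gs_amplitude_uv)
        gains <- 1 + stats::runif(n_channels(rec), -0.1, 0.1)
        i0 <- round(starts[i] * rec$fs) + 1L
        rec$samples <- add_event_to_channels(rec$samples, wave, i0, gains)
        # postictal suppression: attenuate what is already there, ramping back
        ns <- round(config$suppression_dur_s * rec$fs)
        j0 <- i0 + length(wave)
        jdx <- j0:min(j0 + ns - 1L, nrow(rec$samples))
        if (length(jdx) > 1) {
          frac <- seq(0, 1, length.out = length(jdx))
          g <- ifelse(frac < 0.5, config$suppression_factor,
                      config$suppression_factor +
                        (1 - config$suppression_factor) * (frac - 0.5) * 2)
          rec$samples[jdx, ] <- rec$samples[jdx, , drop = FALSE] * g
        }
      }
      truth <- rbind(
        annotations("GS", starts, starts + durs, source = "truth",
                    freq_hz = NA_real_, amp_uv = config$gs_amplitude_uv),
        annotations("suppression", starts + durs,
                    starts + durs + config$suppression_dur_s, source = "truth",
                    freq_hz = NA_real_, amp_uv = NA_real_)
      )
      list(recording = rec, truth = truth[order(truth$start_s), ])
    }
  })
}

#' Inject brief movement artifacts
#'
#' Adds Poisson-placed high-frequency (> 20 Hz) bursts shorter than 1 s,
#' labeled `artifact` in the truth, never overlapping intervals in `avoid`.
#'
#' @inheritParams inject_swd_trains
#' @return list with `recording` and `truth`.
#' @export
inject_artifacts <- function(rec, config, avoid = NULL) {
  stopifnot_recording(rec)
  dur <- rec_duration_s(rec)
  withr::with_seed(derive_seed(config$seed, 4L), {
    n_events <- stats::rpois(1, config$artifact_rate_per_hour * dur / 3600)
    if (n_events == 0) {
      list(recording = rec, truth = empty_annotations())
    } else {
      durs <- stats::runif(n_events, 0.2, 0.8)
      freqs <- stats::runif(n_events, 30, 60)
      starts <- place_events(n_events, dur, durs, avoid = avoid)
      for (i in seq_len(n_events)) {
        wave <- artifact_waveform(freqs[i], durs[i], rec$fs, config$artifact_amplitude_uv)
        gains <- 1 + stats::runif(n_channels(rec), -0.1, 0.1)
        rec$samples <- add_event_to_channels(rec$samples, wave,
                                             round(starts[i] * rec$fs) + 1L, gains)
      }
      truth <- annotations("artifact", starts, starts + durs, source = "truth",
                           freq_hz = freqs, amp_uv = config$artifact_amplitude_uv)
      list(recording = rec, truth = truth[order(truth$start_s), ])
    }
  })
}

#' Generate one synthetic animal recording with all event types
#'
#' Convenience wrapper: baseline, then GS (+ suppression), then SWD trains
#' avoiding GS, then artifacts avoiding both.
#'
#' @inheritParams generate_baseline
#' @return list with `recording` and `truth` (all event types combined,
#'   sorted by onset).
#' @export
synthesize_recording <- function(config, animal_id = "synthetic",
                                 group_label = NA_character_) {
  rec <- generate_baseline(config, animal_id, group_label)
  gs <- inject_gs(rec, config)
  swd <- inject_swd_trains(gs$recording, config, avoid = gs$truth)
  art <- inject_artifacts(swd$recording, config,
                          avoid = rbind(gs$truth, swd$truth))
  truth <- rbind(gs$truth, swd$truth, art$truth)
  truth <- truth[order(truth$start_s), ]
  rownames(truth) <- NULL
  list(recording = art$recording, truth = truth)
}

#' Generate a seeded synthetic cohort
#'
#' Builds one recording per animal across groups, each with ground truth and
#' a truth summary row (planted rates) for parameter-recovery checks.
#' Per-animal seeds are derived deterministically from the master seed.
#'
#' @param group_specs list of specs, each a list with `group_label`,
#'   `n_animals` and `config` (an `eeg_genconfig`).
#' @param seed master integer seed.
#' @return list with `animals` (list of `recording`/`truth`/`summary_truth`)
#'   and `manifest` (one data.frame row per animal).
#' @export
generate_cohort <- function(group_specs, seed = 1L) {
  labels <- vapply(group_specs, function(g) g$group_label, character(1))
  if (anyDuplicated(labels)) stop("duplicate group labels in cohort spec")
  if (any(vapply(group_specs, function(g) g$n_animals < 1, logical(1))))
    stop("each group needs at least one animal")
  animals <- list()
  manifest <- NULL
  k <- 0L
  for (g in group_specs) {
    for (a in seq_len(g$n_animals)) {
      k <- k + 1L
      cfg <- g$config
      cfg$seed <- derive_seed(seed, k * 7L)
      id <- sprintf("%s-%02d", g$group_label, a)
      sim <- synthesize_recording(cfg, animal_id = id, group_label = g$group_label)
      hours <- rec_duration_s(sim$recording) / 3600
      tr <- sim$truth
      summary_truth <- data.frame(
        animal_id = id, group_label = g$group_label, total_hours = hours,
        true_gs_count = sum(tr$event_type == "GS"),
        true_swd_count = sum(tr$event_type == "SWD"),
        true_gs_rate_per_day = sum(tr$event_type == "GS") / (hours / 24),
        true_swd_rate_per_hour = sum(tr$event_type == "SWD") / hours,
        planted_gs_rate_per_day = cfg$gs_rate_per_day,
        planted_swd_rate_per_hour = cfg$swd_rate_per_hour,
        seed = cfg$seed, stringsAsFactors = FALSE)
      animals[[id]] <- list(recording = sim$recording, truth = tr,
                            summary_truth = summary_truth)
      manifest <- rbind(manifest, summary_truth)
    }
  }
  list(animals = animals, manifest = manifest)
}
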