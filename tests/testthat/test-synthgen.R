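test_that("baseline generation is deterministic with the configured length and RMS", {
  cfg <- generator_config(duration_s = 10, seed = 4)
  r1 <- generate_baseline(cfg)
  r2 <- generate_baseline(cfg)
  expect_identical(r1$samples, r2$samples)
  expect_equal(dim(r1$samples), c(2560L, 3L))
  expect_equal(apply(r1$samples, 2, function(x) sqrt(mean(x^2))),
               rep(40, 3), tolerance = 1e-12)
  r3 <- generate_baseline(generator_config(duration_s = 10, seed = 5))
  expect_false(identical(r1$samples, r3$samples))
  # zero-power configuration
  z <- generate_baseline(generator_config(duration_s = 10, baseline_rms = 0))
  expect_true(all(z$samples == 0))
})

test_that("baseline spectrum falls as 1/f^alpha", {
  cfg <- generator_config(duration_s = 120, spectral_exponent = 1, seed = 1)
  rec <- generate_baseline(cfg)
  p <- welch_psd(rec$samples[, 1], cfg$fs)
  sel <- p$freq >= 2 & p$freq <= 20
  slope <- unname(stats::coef(stats::lm(log10(p$psd[sel]) ~ log10(p$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("invalid generator configurations are rejected by field", {
  expect_error(generator_config(fs = -1), "fs")
  expect_error(generator_config(swd_freq_hz = c(4, 6)), "swd_freq_hz")
  expect_error(generator_config(swd_dur_s = c(2, 5)), "swd_dur_s")
  expect_error(generator_config(suppression_factor = 1.5), "suppression_factor")
  expect_error(generator_config(swd_rate_per_hour = -2), "swd_rate_per_hour")
})

test_that("SWD injection plants 5-7 Hz trains of at least 3 s without touching the rest", {
  cfg <- generator_config(duration_s = 1800, swd_rate_per_hour = 12,
                          gs_rate_per_day = 0, artifact_rate_per_hour = 0, seed = 7)
  base <- generate_baseline(cfg)
  # zero rate leaves the recording unchanged
  cfg0 <- generator_config(duration_s = 1800, swd_rate_per_hour = 0, seed = 7)
  sw0 <- inject_swd_trains(base, cfg0)
  expect_identical(sw0$recording$samples, base$samples)
  expect_equal(nrow(sw0$truth), 0L)

  sw <- inject_swd_trains(base, cfg)
  sw_rep <- inject_swd_trains(base, cfg)
  expect_identical(sw$recording$samples, sw_rep$recording$samples)
  tr <- sw$truth
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$end_s - tr$start_s >= 3))
  expect_true(all(tr$freq_hz >= 5 & tr$freq_hz <= 7))
  # trains do not overlap each other
  tr <- tr[order(tr$start_s), ]
  if (nrow(tr) > 1) expect_true(all(tr$start_s[-1] >= tr$end_s[-nrow(tr)]))
  # dominant PSD frequency of each inserted segment lies in the 5-7 Hz band
  for (i in seq_len(nrow(tr))) {
    seg <- sw$recording$samples[round(tr$start_s[i] * cfg$fs):round(tr$end_s[i] * cfg$fs), 1]
    p <- welch_psd(seg, cfg$fs, n_segments = 2)
    pk <- p$freq[which.max(p$psd)]
    expect_gte(pk, 5); expect_lte(pk, 7)
  }
  # additive events: the signal outside annotated intervals equals baseline
  mask <- rep(TRUE, nrow(base$samples))
  for (i in seq_len(nrow(tr))) {
    i0 <- max(1, floor(tr$start_s[i] * cfg$fs))
    i1 <- min(nrow(base$samples), ceiling(tr$end_s[i] * cfg$fs) + 1)
    mask[i0:i1] <- FALSE
  }
  expect_identical(sw$recording$samples[mask, ], base$samples[mask, ])
})

test_that("GS injection reaches the configured amplitude and suppresses the postictal signal", {
  cfg <- generator_config(duration_s = 7200, gs_rate_per_day = 40,
                          swd_rate_per_hour = 0, artifact_rate_per_hour = 0,
                          suppression_factor = 0.2, seed = 13)
  base <- generate_baseline(cfg)
  cfg0 <- generator_config(duration_s = 7200, gs_rate_per_day = 0, seed = 11)
  g0 <- inject_gs(base, cfg0)
  expect_identical(g0$recording$samples, base$samples)
  expect_equal(nrow(g0$truth), 0L)

  sim <- inject_gs(base, cfg)
  tr <- sim$truth[sim$truth$event_type == "GS", ]
  expect_gt(nrow(tr), 0)
  fs <- cfg$fs
  for (i in seq_len(nrow(tr))) {
    idx <- round(tr$start_s[i] * fs):round(tr$end_s[i] * fs)
    expect_gte(max(abs(sim$recording$samples[idx, 1])), 0.9 * cfg$gs_amplitude_uv)
    if (tr$start_s[i] < 30) next  # no full pre-event window to compare
    # postictal RMS drops below half the pre-event RMS
    e0 <- round(tr$end_s[i] * fs)
    post <- sim$recording$samples[(e0 + 1):(e0 + 30 * fs), 1]
    pre <- sim$recording$samples[(round(tr$start_s[i] * fs) - 30 * fs):
                                   (round(tr$start_s[i] * fs) - 1), 1]
    expect_lt(sqrt(mean(post^2)) / sqrt(mean(pre^2)), 0.5)
  }
  # suppression windows are annotated right after each GS
  sup <- sim$truth[sim$truth$event_type == "suppression", ]
  expect_equal(nrow(sup), nrow(tr))
})

test_that("artifacts are brief high-frequency bursts", {
  cfg <- generator_config(duration_s = 3600, gs_rate_per_day = 0,
                          swd_rate_per_hour = 0, artifact_rate_per_hour = 6, seed = 9)
  base <- generate_baseline(cfg)
  sim <- inject_artifacts(base, cfg)
  tr <- sim$truth
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$end_s - tr$start_s < 1))
  a <- tr[which.max(tr$end_s - tr$start_s), ]
  seg <- sim$recording$samples[round(a$start_s * cfg$fs):round(a$end_s * cfg$fs), 1]
  p <- welch_psd(seg, cfg$fs, n_segments = 2)
  expect_gt(p$freq[which.max(p$psd)], 20)
})

test_that("truth events of different types never overlap within an animal", {
  for (sd in c(1, 2, 3)) {
    cfg <- generator_config(duration_s = 3600, gs_rate_per_day = 30,
                            swd_rate_per_hour = 15, artifact_rate_per_hour = 10,
                            seed = sd)
    sim <- synthesize_recording(cfg)
    ev <- sim$truth[sim$truth$event_type %in% c("GS", "SWD", "artifact"), ]
    ev <- ev[order(ev$start_s), ]
    if (nrow(ev) > 1)
      expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
    expect_true(all(ev$start_s >= 0 & ev$end_s <= rec_duration_s(sim$recording)))
  }
})

test_that("cohort generation reproduces the five-group design and plants recoverable rates", {
  cfg <- generator_config(duration_s = 600, swd_rate_per_hour = 2,
                          gs_rate_per_day = 0, artifact_rate_per_hour = 0)
  specs <- mapply(function(lab, n) list(group_label = lab, n_animals = n, config = cfg),
                  c("Control", "Pten", "PtenRap", "PtenRic", "PtRapRic"),
                  c(9, 7, 6, 7, 6), SIMPLIFY = FALSE)
  co <- generate_cohort(specs, seed = 21)
  expect_equal(length(co$animals), 35L)
  expect_equal(nrow(co$manifest), 35L)
  expect_equal(as.vector(table(factor(co$manifest$group_label,
                                      levels = c("Control", "Pten", "PtenRap",
                                                 "PtenRic", "PtRapRic")))),
               c(9, 7, 6, 7, 6))
  # reproducible under the master seed
  co2 <- generate_cohort(specs, seed = 21)
  expect_identical(co$animals[[1]]$recording$samples,
                   co2$animals[[1]]$recording$samples)
  expect_error(generate_cohort(list(specs[[1]], specs[[1]]), seed = 1), "duplicate")

  # planted-rate recovery: n = 20 animals x 2 h at 10 SWD/h; the mean truth
  # rate must fall within 3 Poisson standard errors of the planted rate
  cfgr <- generator_config(duration_s = 7200, swd_rate_per_hour = 10,
                           gs_rate_per_day = 0, artifact_rate_per_hour = 0)
  cor <- generate_cohort(list(list(group_label = "g", n_animals = 20, config = cfgr)),
                         seed = 5)
  mean_rate <- mean(cor$manifest$true_swd_rate_per_hour)
  se <- sqrt(10 / (20 * 2))
  expect_lt(abs(mean_rate - 10), 3 * se)
})
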