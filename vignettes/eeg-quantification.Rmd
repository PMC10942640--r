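---
title: "Quantifying seizures, spike-and-wave discharges, and interictal EEG in rodent recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seizures, spike-and-wave discharges, and interictal EEG in rodent recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegquant)
```

## What this package computes

`eegquant` quantifies epileptic brain activity in chronic rodent video-EEG:
three epidural channels sampled at 256 Hz over days of recording per animal.
Two event classes dominate in models of cortical mTOR-pathway
hyperactivation:

* **Generalized seizures (GS)** — high-amplitude polyspike events lasting
  tens of seconds, often followed by postictal voltage suppression.
* **Spike-and-wave discharges (SWD)** — rhythmic 5–7 Hz spike-wave trains
  lasting 3 s or more, the most frequent epileptiform event in these
  models.

Around the event detectors the package computes interictal (between-event)
summary measures on evenly sampled 5 s epochs — line length ("coastline"),
mean absolute amplitude, and Welch power spectral density integrated into
1 Hz bands from 1 to 30 Hz — and a statistics battery that compares
animal-level endpoints across experimental groups with the gated test
dispatch described below.

Because chronic EEG datasets are rarely shareable, the package also ships a
seeded synthetic generator that plants all event classes with ground-truth
annotations, so every stage of the pipeline is verifiable end to end.

## Candidate-seizure flagging

The screening rule flags any contiguous, non-overlapping 10 s epoch in
which the absolute signal exceeds **400 µV at two time points at least 1 s
apart** on any single channel (`flag_high_amplitude_epochs()`). Reading
"signal amplitude" per channel rather than requiring simultaneous
crossings on all channels is the conservative choice: it can only flag
more, never fewer, candidate epochs. Because epochs tile the recording
without overlap, a spike pair straddling an epoch boundary can be missed —
the same behaviour as a fixed-epoch screener, and the reason the flags are
a *screen*, not a detector.

A complementary screen (`flag_low_amplitude_epochs()`) searches for
persistent abnormally low amplitude, the signature of postictal
suppression. No published threshold exists for "abnormally low", so the
defaults are package decisions: windows of 1 s RMS (averaged across
channels) must stay below **25 % of the session median RMS** for at least
**30 s**. The threshold is relative, so a recording that is quiet
throughout produces no flags; only sessions of at least 10 minutes are
screened so the median is meaningful.

## From flags to GS events

In the original workflow flagged traces were reviewed by a blinded human
rater who marked seizure onsets and offsets. `review_flags_to_gs()` is an
automated surrogate for that step, stated as such: each flagged epoch is
expanded to the maximal surrounding run of 1 s windows whose channel-mean
line length exceeds 3× the session median, runs closer than 5 s are
merged, and intervals shorter than 10 s or overlapping labeled artifacts
are discarded. Line length is used for boundary refinement because it is
the screening feature already in play, not a new statistic. Manually
marked annotations can be imported through `read_annotations()` and used
everywhere detected events are; the surrogate is validated only against
synthetic ground truth.

GS events longer than 45 s are tallied separately
(`classify_gs_lengths()`), matching the length classification used for
the published cohorts.

## SWD detection

`detect_swd()` implements, per channel:

1. **Spike picking.** Local extrema of $|x - \mathrm{median}(x)|$ whose
   robust z-score (MAD-scaled) exceeds `swd_spike_z` (default 4). Extrema
   closer together than the shortest in-band complex period are
   deduplicated to the largest — two genuine complexes of a 5–7 Hz train
   can never be closer than $(1/7)\,\mathrm{s}\times0.9$, so anything
   closer is a wave component or noise riding on the same complex.
2. **Chaining.** Consecutive spikes whose intervals fall in the period
   band $[1/7, 1/5]$ s widened by ±10 % are chained; one interruption of
   up to two long periods is tolerated per train (`swd_max_gap_complexes
   = 1`), absorbing a single missed or displaced complex.
3. **Duration gate.** A chain is an SWD if the train — from the start of
   the first complex to the end of the last, i.e. the spike span plus one
   inter-spike interval — lasts at least 3 s and contains at least
   $\lceil 5 \times 3 \rceil = 15$ spikes.
4. **Merging and exclusion.** Events overlapping across channels are
   merged (union of intervals); events overlapping a detected GS or a
   labeled artifact are dropped.

The emitted interval extends half a median inter-spike interval beyond the
first and last spike, which keeps onsets within a fraction of a cycle of
the true train onset.

## Interictal metrics

Baseline measures are computed on **692 evenly spaced 5 s epochs per
24 h** (the same density is preserved for shorter recordings via
`scaled_sampling_plan()`; plans that would overlap epochs are rejected).
Epochs overlapping any GS, SWD, artifact, or suppression interval are
excluded *before* averaging, and both the retained and excluded counts are
reported so either accounting convention can be reconstructed.

* **Line length** $\sum_i |x_{i+1} - x_i|$ — absolute first differences,
  the standard coastline feature. The constant sampling interval means a
  Euclidean reading (including the time axis) would only add an offset.
* **Mean amplitude** $\frac1n \sum_i |x_i|$.
* **Welch PSD** — the segmentation convention of the MATLAB `pwelch`
  default is pinned for reproducibility: 8 segments, 50 % overlap, Hamming
  window, one-sided density in µV²/Hz, no detrending. On a 5 s epoch at
  256 Hz this gives 284-sample segments and a 0.90 Hz resolution, enough
  for 1 Hz band integration. The estimator satisfies discrete Parseval
  (integral of the density ≈ mean square) within a few percent on
  stationary noise. When segments do not tile the signal exactly the
  trailing remainder is discarded, so time-reversal invariance of the PSD
  is only approximate (well under 1 %); the sample-wise metrics are exactly
  reversal-invariant.
* **Band powers** — band $k$ integrates the density over the half-open bin
  $[k-0.5, k+0.5)$ Hz for $k = 1..30$; total power sums the bands and
  relative power divides by the total. The half-open convention makes the
  bands a partition; no published edge convention exists.

All three channels are analyzed; each per-epoch metric is the mean over
channels, per-animal values are means over retained epochs, and the
cumulative coastline is the sum over retained epochs of the channel-mean
line length.

## Event rates

GS rates are events per recorded day; SWD rates are events per hour.
`compute_event_rates()` supports two SWD conventions: `full` (count ÷
recorded hours) and `subsampled`, which reproduces the review scheme of
eight evenly spaced 1 h epochs in each of two 24 h sessions (16 sampled
hours; an event counts when its onset falls in a sampled hour). For
recordings shorter than two full sessions the scheme degrades gracefully
to proportional subsampling at the same one-hour-in-three density, with a
warning.

## Statistical dispatch

`dispatch_omnibus()` reproduces the analysis protocol as a pure function
of the data at α = 0.05:

1. **Normality gate.** Shapiro–Wilk per group. Groups with fewer than 3
   observations, or constant values, cannot be tested and contribute no
   evidence — the protocol statement ("all data distributions were
   assessed") does not fix the granularity, and per-group testing is the
   convention of the graphing software named in the protocol.
2. If any group rejects normality → **Kruskal–Wallis** with mid-ranks and
   the classic tie correction $H / \bigl(1 - \sum(t^3-t)/(N^3-N)\bigr)$
   (required to reproduce the published statistic from a table with 27
   tied zeros), with **Dunn** z-tests on mean ranks, Bonferroni-adjusted
   and capped at 1.
3. Otherwise **Brown–Forsythe** (Levene on absolute deviations from group
   medians, via `car::leveneTest(center = median)`); unequal variances →
   **Welch's ANOVA**. The protocol names no post hoc for this branch;
   Games–Howell is provided and labeled as a package choice.
4. Otherwise classic **one-way ANOVA with Tukey HSD**.

Binary GS occurrence is modeled with a logistic GLM on the group factor
(`occurrence_glm()`). Cohorts in which no (or every) animal has a seizure
cause quasi-separation; the model is then refit with Firth's penalized
likelihood and flagged, and pairwise contrasts use penalized
likelihood-ratio tests (Wald statistics are unstable under separation).
The statistical package used in the original analysis reports a much
larger Wald statistic in this regime; that behaviour is a known artifact
of maximum likelihood under quasi-separation and is deliberately not
reproduced — the penalized fit is the defensible one, and the ordering
and significance of the affected contrast are preserved before
correction.

Per-band power is compared with a two-way ANOVA (group × band, animals as
replicates) with Tukey-adjusted group contrasts within each band
(`psd_twoway_anova()`, via emmeans), producing the 30-row per-band
p-value layout for total and relative power.

For the published monitoring table, the control cohort pools littermate
and wild-type-background control animals (n = 9), which is what the
published group means require.

## The synthetic generator

`generator_config()` defaults describe the recording conditions the
pipeline assumes; each parameter is a study condition, not a tuning knob:

| parameter | default | rationale |
|---|---|---|
| `fs`, `n_channels` | 256 Hz, 3 | acquisition hardware of the protocol |
| `baseline_rms` | 40 µV | gives a mean absolute amplitude of ≈ 32 µV (Gaussian: $\sqrt{2/\pi}\,\mathrm{RMS}$), matching control-animal interictal amplitude |
| `spectral_exponent` | 2 | typical 1/f² falloff of rodent epidural EEG over 1–30 Hz |
| `gs_rate_per_day`, `gs_dur_s`, `gs_amplitude_uv` | 0.5/day, 20–60 s, 600 µV | seizure-positive animals show fractions of an event per day; durations bracket the 45 s length threshold; amplitude comfortably exceeds the 400 µV screen |
| `suppression_factor`, `suppression_dur_s` | 0.3, 60 s | postictal suppression visible to the low-amplitude screen; second half ramps linearly back (no published functional form) |
| `swd_rate_per_hour`, `swd_freq_hz`, `swd_dur_s`, `swd_amplitude_uv` | 10/h, 5–7 Hz, 3–8 s, 300 µV | affected-cohort rates are ≈ 7–11/h with ≈ 5 s mean train length; amplitude ≈ 7 MAD above background, below the GS screen |
| `artifact_rate_per_hour` | 2/h | occasional chewing/scratching bursts, < 1 s, > 20 Hz |

The SWD waveform is a periodic sharp transient riding on a half-wave —
harmonic-rich on purpose, so spike-picking detectors face realistic
morphology rather than a sinusoid; the complex is AC-coupled (zero-mean)
and the spike peak is ≈ 2.5× the wave trough, so wave components sit below
the spike-picking threshold at the default amplitude. The GS stand-in is
polyspike activity with a slowly wandering 4–10 Hz instantaneous frequency
under a rise/fall envelope; no quantitative published GS morphology
exists, so this waveform is a stand-in and automated GS boundaries are
validated only against synthetic truth. Events are placed by uniform
proposal with rejection on overlap (bounded at 1000 retries; impossible
densities raise an error); every channel receives the same waveform with
±10 % per-channel gain jitter; suppression attenuates whatever signal is
present. Everything is deterministic given the config seed, with separate
derived streams per synthesis stage, so a baseline and its event-bearing
counterpart agree exactly outside event intervals.

What the generator does **not** emulate: sleep architecture and
circadian rate modulation, electrode drift, non-stationary artifact
families, and inter-channel propagation delays. Passing detection tests
on synthetic cohorts therefore demonstrates correctness of the rules, not
field performance on real recordings.

## File formats

Recordings travel as EDF (16-bit, one data record per second, physical
range ±2000 µV by default — headroom above the 400 µV screen and GS
amplitudes, with a ≈ 0.06 µV quantization step). Whole-second recordings
and an integer sampling rate are required; EDF+ embedded annotations are
out of scope. Events travel as delimited text (type, start, end, scope,
source; half-open `[start_s, end_s)` seconds from recording start, full
double precision so round trips are exact).

## Verification scale

The shipped tests exercise the pipeline at sizes chosen to keep the suite
fast while leaving no stage untested: detection accuracy on a five-group
cohort of 4 animals × 2 h at the published group rates (recall and
precision ≥ 0.9 at 0.5 s onset tolerance), planted-rate recovery within 3
Poisson standard errors, brute-force oracle equality for the amplitude
screen and the sample-wise metrics, Parseval and tone-localization checks
for the spectral path, and 2000-replicate null calibration of the test
dispatch (type-I error within [0.03, 0.07] at α = 0.05).
`scripts/acceptance.R` recomputes the headline quantities from scratch on
a 5 × 2 × 1 h cohort.

## Known limitations

* Automated GS marking approximates a human rater; boundary conventions
  differ from rater habits, so absolute GS lengths on real data should be
  anchored by imported manual annotations.
* The Welch PSD inherits the pinned `pwelch` segmentation; other
  conventions shift absolute band powers slightly (relative powers are
  insensitive).
* The occurrence GLM deliberately replaces maximum likelihood under
  separation with a penalized fit (see above).
* Tests of detector performance are against the generator's morphology;
  thresholds (`swd_spike_z`, line-length expansion factor) may need
  recalibration for other acquisition systems.
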