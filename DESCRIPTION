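Package: eegquant
Title: Seizure and Spike-and-Wave Discharge Quantification for Rodent Video-EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies epileptic brain activity in continuous rodent EEG
    recordings. Implements amplitude/line-length candidate-seizure flagging,
    detection of 5-7 Hz spike-and-wave discharge (SWD) trains, interictal
    metrics (line length/coastline, mean absolute amplitude, Welch power
    spectral density and 1-30 Hz band powers) on evenly sampled 5 s epochs
    with three-channel averaging, per-animal event-rate summaries, and a
    statistical dispatch battery (Shapiro-Wilk and Brown-Forsythe gates
    selecting classic ANOVA/Tukey, Welch ANOVA, or Kruskal-Wallis/Dunn, plus
    a binary-logistic occurrence model and per-band two-way ANOVA). A seeded
    synthetic-EEG generator plants generalized seizures, SWD trains,
    postictal suppression, and movement artifacts with ground-truth
    annotations so every pipeline stage is testable without animal
    recordings. Recordings are read and written as European Data Format
    (EDF) files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car,
    emmeans,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
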