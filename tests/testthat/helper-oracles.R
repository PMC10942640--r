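# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) pairwise-timepoint scan of the amplitude screen: returns the start
# times of flagged epochs on a single channel.
oracle_flag_high <- function(x, fs, thr = 400, epoch_s = 10, sep_s = 1) {
  n_ep <- floor(length(x) / (epoch_s * fs))
  flagged <- numeric(0)
  for (e in seq_len(n_ep) - 1) {
    idx <- (e * epoch_s * fs + 1):((e + 1) * epoch_s * fs)
    hit <- idx[abs(x[idx]) > thr]
    ok <- FALSE
    if (length(hit) >= 2) {
      for (i in seq_along(hit)) {
        for (j in seq_along(hit)) {
          if (abs(hit[i] - hit[j]) / fs >= sep_s) { ok <- TRUE; break }
        }
        if (ok) break
      }
    }
    if (ok) flagged <- c(flagged, e * epoch_s)
  }
  flagged
}

oracle_line_length <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

oracle_mean_amplitude <- function(x) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i])
  s / length(x)
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_F <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); N <- length(all_v)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Tie-corrected Kruskal-Wallis H from explicit mid-ranks.
oracle_kw_H <- function(groups) {
  all_v <- unlist(groups)
  N <- length(all_v)
  r <- rank(all_v)  # mid-ranks
  idx <- cumsum(c(0, vapply(groups, length, numeric(1))))
  h <- 0
  for (i in seq_along(groups)) {
    ri <- r[(idx[i] + 1):idx[i + 1]]
    h <- h + length(ri) * (mean(ri) - (N + 1) / 2)^2
  }
  h <- 12 * h / (N * (N + 1))
  ties <- table(all_v)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Per-animal rate table of the five published cohorts.
load_rate_fixture <- function() {
  read_rate_table(system.file("extdata", "table1_rates.csv", package = "eegquant"))
}

quiet_rates <- function(...) suppressWarnings(compute_event_rates(...))
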