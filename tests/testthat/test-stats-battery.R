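swd_table <- function() {
  rt <- load_rate_fixture()
  data.frame(animal_id = rt$animal_id, group = rt$group, value = rt$swd_rate_per_hour)
}
gs_table <- function() {
  rt <- load_rate_fixture()
  data.frame(animal_id = rt$animal_id, group = rt$group, value = rt$gs_rate_per_day)
}

test_that("group summaries reproduce the published SWD and GS cohort means", {
  gs <- group_summary(swd_table())
  m <- setNames(gs$mean, gs$group)
  printed <- c(Control = 0.292, Pten = 10.5, PtenRap = 9.41,
               PtenRic = 6.66, PtRapRic = 0.563)
  ulp <- c(0.001, 0.1, 0.01, 0.01, 0.001)  # unit of the last printed digit
  expect_true(all(abs(m[names(printed)] - printed) <= ulp / 2 + 1e-12))
  gg <- group_summary(gs_table())
  expect_equal(unname(round(gg$mean[gg$group == "Pten"], 3)), 0.470)
  expect_equal(unname(gg$mean[gg$group == "Control"]), 0)
  expect_equal(unname(gg$sem[gg$group == "Control"]), 0)
  single <- data.frame(group = c("a", "a", "b"), value = c(1, 2, 5))
  s <- group_summary(single)
  expect_true(s$sem_undefined[s$group == "b"])
})

test_that("one-way ANOVA matches the sum-of-squares oracle and the published F", {
  tb <- swd_table()
  res <- anova_oneway(tb)
  expect_equal(res$statistic, oracle_anova_F(split(tb$value, tb$group)),
               tolerance = 1e-9)
  expect_equal(round(res$statistic, 2), 32.36)
  expect_lt(res$p_value, 1e-4)

  tb2 <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                    value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
  expect_equal(anova_oneway(tb2)$statistic,
               oracle_anova_F(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))),
               tolerance = 1e-12)
  ident <- data.frame(group = rep(c("a", "b"), each = 3), value = rep(c(1, 2, 3), 2))
  expect_equal(anova_oneway(ident)$statistic, 0)
  expect_error(anova_oneway(data.frame(group = rep(c("a", "b"), each = 2),
                                       value = c(1, 1, 2, 2))), "variance")
})

test_that("tie-corrected Kruskal-Wallis matches the rank oracle and the published K", {
  tb <- gs_table()
  res <- kruskal_wallis(tb)
  expect_equal(res$statistic, oracle_kw_H(split(tb$value, tb$group)),
               tolerance = 1e-9)
  expect_equal(round(res$statistic, 3), 9.475)

  tb2 <- data.frame(group = rep(c("a", "b"), each = 2), value = c(1, 2, 3, 4))
  expect_equal(kruskal_wallis(tb2)$statistic, oracle_kw_H(list(c(1, 2), c(3, 4))),
               tolerance = 1e-12)
  ident <- data.frame(group = rep(c("a", "b"), each = 2), value = c(1, 2, 1, 2))
  expect_equal(kruskal_wallis(ident)$statistic, 0, tolerance = 1e-12)
  const <- data.frame(group = rep(c("a", "b"), each = 2), value = rep(1, 4))
  expect_true(is.na(kruskal_wallis(const)$statistic))
})

test_that("the omnibus dispatch selects the protocol's test for each data shape", {
  withr::with_seed(5, {
    gauss <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                        value = stats::rnorm(30))
    expect_equal(dispatch_omnibus(gauss, posthoc = FALSE)$test_used, "ANOVA_Tukey")
    hetero <- data.frame(group = rep(c("a", "b", "c"), each = 15),
                         value = c(stats::rnorm(15, 0, 1),
                                   stats::rnorm(15, 0, sqrt(10)),
                                   stats::rnorm(15, 0, 1)))
    expect_equal(dispatch_omnibus(hetero, posthoc = FALSE)$test_used, "Welch_ANOVA")
  })
  # heavily tied zero-inflated data (the GS rates) -> Kruskal-Wallis/Dunn
  d <- dispatch_omnibus(gs_table())
  expect_equal(d$test_used, "KruskalWallis_Dunn")
  expect_equal(nrow(d$posthoc), choose(5, 2))
  # same table in, same branch out
  expect_equal(dispatch_omnibus(gs_table())$test_used, d$test_used)
  const <- data.frame(group = rep(c("a", "b"), each = 3), value = 1)
  expect_equal(dispatch_omnibus(const)$test_used, "degenerate")
})

test_that("post hoc adjustments are valid probabilities, monotone, and capped", {
  d <- posthoc_pairwise(gs_table(), "dunn")
  expect_true(all(d$p_adj >= d$p_unadj - 1e-12))
  expect_true(all(d$p_adj >= 0 & d$p_adj <= 1))
  expect_true(any(d$p_adj == 1))  # ties push several comparisons to the cap
  tk <- posthoc_pairwise(swd_table(), "tukey")
  expect_equal(nrow(tk), choose(5, 2))
  # two groups: the single Tukey comparison equals the unadjusted ANOVA p
  two <- data.frame(group = rep(c("a", "b"), each = 6),
                    value = c(1.2, 2.1, 1.7, 2.4, 1.9, 2.2, 3.1, 2.8, 3.4, 2.9, 3.6, 3.0))
  tk2 <- posthoc_pairwise(two, "tukey")
  expect_equal(nrow(tk2), 1L)
  expect_equal(tk2$p_adj, anova_oneway(two)$p_value, tolerance = 1e-6)
  gh <- posthoc_pairwise(swd_table(), "games_howell")
  expect_true(all(gh$p_adj >= 0 & gh$p_adj <= 1))
})

test_that("the occurrence model flags separation and ranks the affected cohort first", {
  rt <- load_rate_fixture()
  occ <- data.frame(group = rt$group, value = as.numeric(rt$gs_rate_per_day > 0))
  g <- occurrence_glm(occ)
  expect_true(g$separation)  # two all-zero cohorts
  expect_equal(nrow(g$pairwise), choose(5, 2))
  conpten <- g$pairwise$p_unadj[g$pairwise$comparison == "Control - Pten"]
  expect_equal(which.min(g$pairwise$p_unadj),
               which(g$pairwise$comparison == "Control - Pten"))
  expect_lt(conpten, 0.05)
  # no-event data: all pairwise p = 1
  g0 <- occurrence_glm(data.frame(group = rep(c("a", "b", "c"), each = 4), value = 0))
  expect_true(all(g0$pairwise$p_adj == 1))
  # complete separation in a two-group design
  g2 <- occurrence_glm(data.frame(group = rep(c("a", "b"), each = 5),
                                  value = rep(0:1, each = 5)))
  expect_true(g2$separation)
  expect_lt(g2$pairwise$p_adj, 0.05)
  expect_error(occurrence_glm(data.frame(group = "a", value = c(0, 1))), "2 groups")
})

test_that("per-band two-way ANOVA isolates a shifted band", {
  withr::with_seed(14, {
    mk <- function(shift6, glab, n = 8) do.call(rbind, lapply(seq_len(n), function(a)
      data.frame(animal_id = paste0(glab, a), group = glab, band = 1:30,
                 value = stats::rnorm(30, 10, 1) + ifelse(1:30 == 6, shift6, 0))))
    bt <- rbind(mk(0, "g1"), mk(5, "g2"))
    res <- psd_twoway_anova(bt)
    expect_equal(nrow(res$pairwise_p), 30L)
    expect_lt(res$pairwise_p[res$pairwise_p$band == 6, 2], 0.05)
    others <- res$pairwise_p[res$pairwise_p$band != 6, 2]
    expect_gte(sum(others >= 0.05), 27)
  })
  expect_error(psd_twoway_anova(data.frame(group = "a", band = 1, value = 1)),
               "bands 1-30")
})
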