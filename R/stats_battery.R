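#' Group mean and SEM table
#'
#' @param table data.frame with at least `group` and `value` columns
#'   (optionally `animal_id`); one row per animal.
#' @return data.frame with `group`, `n`, `mean`, `sem` (SD/sqrt(n); NA with
#'   a flag for n = 1) and `sem_undefined`.
#' @export
group_summary <- function(table) {
  check_group_table(table)
  groups <- unique(table$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- table$value[table$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               sem_undefined = length(v) == 1, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

check_group_table <- function(table, min_groups = 2) {
  if (!is.data.frame(table) || !all(c("group", "value") %in% names(table)))
    stop("expected a data.frame with 'group' and 'value' columns")
  if (anyNA(table$value)) stop("group table contains missing values")
  if (length(unique(table$group)) < min_groups)
    stop("need at least ", min_groups, " groups")
  if (nrow(table) < 2) stop("need at least 2 observations")
  invisible(table)
}

#' Classic one-way ANOVA
#'
#' Fixed-effects F test (between-group over within-group mean square).
#'
#' @param table group/value data.frame.
#' @return list with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(table) {
  check_group_table(table)
  g <- factor(table$group)
  if (all(vapply(split(table$value, g), function(v) stats::var(v) == 0, logical(1))))
    stop("zero within-group variance in every group; F undefined")
  ft <- stats::oneway.test(value ~ group, data = transform(table, group = g),
                           var.equal = TRUE)
  list(statistic = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p_value = unname(ft$p.value))
}

#' Welch's ANOVA (unequal variances)
#'
#' @param table group/value data.frame.
#' @return list with `statistic` (W), `df1`, `df2`, `p_value`.
#' @export
anova_welch <- function(table) {
  check_group_table(table)
  ft <- stats::oneway.test(value ~ factor(group), data = table, var.equal = FALSE)
  list(statistic = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p_value = unname(ft$p.value))
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based omnibus H with mid-ranks for ties and the classic correction
#' H / (1 - sum(t^3 - t) / (N^3 - N)).
#'
#' @param table group/value data.frame.
#' @return list with `statistic` (H), `df`, `p_value`; when all values are
#'   identical the statistic is undefined and `note` explains why.
#' @export
kruskal_wallis <- function(table) {
  check_group_table(table)
  if (length(unique(table$value)) == 1)
    return(list(statistic = NA_real_, df = length(unique(table$group)) - 1,
                p_value = NA_real_,
                note = "all values identical; tie correction denominator is 0"))
  kt <- stats::kruskal.test(table$value, factor(table$group))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = unname(kt$p.value))
}

#' Brown-Forsythe variance-homogeneity test
#'
#' Levene's test on absolute deviations from the group medians.
#'
#' @param table group/value data.frame.
#' @return list with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
brown_forsythe <- function(table) {
  check_group_table(table)
  # degenerate tables (identical absolute deviations) give NaN: treated by
  # callers as "no evidence of unequal variance"
  lt <- suppressWarnings(
    car::leveneTest(table$value, factor(table$group), center = stats::median))
  list(statistic = lt$`F value`[1], df1 = lt$Df[1], df2 = lt$Df[2],
       p_value = lt$`Pr(>F)`[1])
}

# Dunn's post hoc z tests on mean ranks with tie correction; adjusted p are
# Bonferroni-style (multiplied by the number of comparisons, capped at 1).
dunn_posthoc <- function(table) {
  g <- factor(table$group)
  r <- rank(table$value)
  N <- length(r)
  ties <- table(table$value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ra <- mean(r[g == a]); rb <- mean(r[g == b])
    na <- sum(g == a); nb <- sum(g == b)
    z <- (ra - rb) / sqrt(v0 * (1 / na + 1 / nb))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = paste(a, b, sep = " - "), estimate = ra - rb,
               statistic = z, p_unadj = p, p_adj = min(1, p * m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

tukey_posthoc <- function(table) {
  fit <- stats::aov(value ~ group, data = transform(table, group = factor(group)))
  tk <- stats::TukeyHSD(fit)$group
  out <- data.frame(comparison = sub("-", " - ", rownames(tk), fixed = TRUE),
                    estimate = tk[, "diff"], statistic = NA_real_,
                    p_unadj = NA_real_, p_adj = tk[, "p adj"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Games-Howell pairwise comparisons after Welch's ANOVA (Welch t with
# studentized-range reference). Not part of the source protocol, which
# leaves the Welch post hoc unspecified.
games_howell_posthoc <- function(table) {
  g <- factor(table$group)
  levs <- levels(g)
  k <- length(levs)
  stats_by <- lapply(levs, function(l) {
    v <- table$value[g == l]
    list(m = mean(v), v = stats::var(v), n = length(v))
  })
  names(stats_by) <- levs
  pairs <- utils::combn(levs, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- stats_by[[pairs[1, j]]]; b <- stats_by[[pairs[2, j]]]
    se2 <- a$v / a$n + b$v / b$n
    t <- (a$m - b$m) / sqrt(se2)
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), k, df, lower.tail = FALSE)
    data.frame(comparison = paste(pairs[1, j], pairs[2, j], sep = " - "),
               estimate = a$m - b$m, statistic = t, p_unadj = NA_real_,
               p_adj = p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise post hoc comparisons
#'
#' All C(k,2) pairs, adjusted for the family matching the omnibus test:
#' Tukey HSD after classic ANOVA, Dunn (Bonferroni-adjusted) after
#' Kruskal-Wallis, Games-Howell after Welch's ANOVA.
#'
#' @param table group/value data.frame.
#' @param family `"tukey"`, `"dunn"`, or `"games_howell"`.
#' @return data.frame with `comparison`, `estimate`, `statistic`,
#'   `p_unadj`, `p_adj`.
#' @export
posthoc_pairwise <- function(table, family = c("tukey", "dunn", "games_howell")) {
  check_group_table(table)
  switch(match.arg(family),
         tukey = tukey_posthoc(table),
         dunn = dunn_posthoc(table),
         games_howell = games_howell_posthoc(table))
}

#' Normality/variance-gated omnibus test dispatch
#'
#' Mirrors the analysis protocol: Shapiro-Wilk per group (groups with fewer
#' than 3 observations or constant values cannot be tested and contribute no
#' evidence); if any group rejects normality at `alpha`, Kruskal-Wallis with
#' Dunn post hoc; otherwise Brown-Forsythe, and on unequal variances Welch's
#' ANOVA (Games-Howell post hoc), else classic one-way ANOVA with Tukey HSD.
#'
#' @param table group/value data.frame.
#' @param alpha gate significance level.
#' @param endpoint label carried into the result.
#' @param posthoc compute the pairwise table (skippable for speed in
#'   simulations).
#' @return object of class `eeg_stat_result`: `endpoint`, `test_used`,
#'   `gate` (Shapiro p per group, Brown-Forsythe p), `statistic`,
#'   `statistic_name`, `df`, `p_value`, `posthoc`, `group_summary`.
#' @export
dispatch_omnibus <- function(table, alpha = 0.05, endpoint = "endpoint",
                             posthoc = TRUE) {
  check_group_table(table)
  g <- factor(table$group)
  if (length(unique(table$value)) == 1) {
    res <- list(endpoint = endpoint, test_used = "degenerate",
                gate = list(shapiro_p = NULL, brown_forsythe_p = NA_real_),
                statistic = NA_real_, statistic_name = NA_character_,
                df = NA_real_, p_value = NA_real_, posthoc = NULL,
                group_summary = group_summary(table),
                note = "all values identical across groups; no test defined")
    class(res) <- "eeg_stat_result"
    return(res)
  }
  shapiro_p <- vapply(levels(g), function(l) {
    v <- table$value[g == l]
    if (length(v) < 3 || length(v) > 5000 || stats::var(v) == 0) NA_real_
    else stats::shapiro.test(v)$p.value
  }, numeric(1))
  non_normal <- any(shapiro_p < alpha, na.rm = TRUE)
  bf_p <- NA_real_
  if (!non_normal) {
    bf <- brown_forsythe(table)
    bf_p <- bf$p_value
  }
  if (non_normal) {
    om <- kruskal_wallis(table)
    test_used <- "KruskalWallis_Dunn"; stat_name <- "K"
    df <- om$df
    ph <- if (posthoc) posthoc_pairwise(table, "dunn") else NULL
  } else if (!is.na(bf_p) && bf_p < alpha) {
    om <- anova_welch(table)
    test_used <- "Welch_ANOVA"; stat_name <- "W"
    df <- c(om$df1, om$df2)
    ph <- if (posthoc) posthoc_pairwise(table, "games_howell") else NULL
  } else {
    om <- anova_oneway(table)
    test_used <- "ANOVA_Tukey"; stat_name <- "F"
    df <- c(om$df1, om$df2)
    ph <- if (posthoc) posthoc_pairwise(table, "tukey") else NULL
  }
  res <- list(endpoint = endpoint, test_used = test_used,
              gate = list(shapiro_p = shapiro_p, brown_forsythe_p = bf_p),
              statistic = om$statistic, statistic_name = stat_name,
              df = df, p_value = om$p_value, posthoc = ph,
              group_summary = group_summary(table))
  class(res) <- "eeg_stat_result"
  res
}

#' @export
print.eeg_stat_result <- function(x, ...) {
  cat(sprintf("%s | %s | %s=%.4g, p=%.4g\n", x$endpoint, x$test_used,
              if (is.na(x$statistic_name)) "stat" else x$statistic_name,
              x$statistic, x$p_value))
  gs <- x$group_summary
  cat(paste(sprintf("  %s: %.3g +/- %.3g (n=%d)", gs$group, gs$mean,
                    gs$sem, gs$n), collapse = "\n"), "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc (adjusted p):\n")
    cat(paste(sprintf("    %s: %.4g", x$posthoc$comparison, x$posthoc$p_adj),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

# Firth-penalized logistic regression (Jeffreys-prior score correction),
# used when maximum likelihood fails to converge under (quasi-)separation.
# Returns the penalized log-likelihood so nested models can be compared with
# a penalized LRT (the recommended test under separation; Wald is unstable).
firth_logit <- function(X, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% b)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XtW <- t(X * W)
    I <- XtW %*% X
    Iinv <- solve(I + diag(1e-10, ncol(X)))
    h <- rowSums((X %*% Iinv) * (X * W))
    U <- as.vector(t(X) %*% (y - p + h * (0.5 - p)))
    step <- as.vector(Iinv %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% b)
  p <- stats::plogis(eta)
  I <- t(X * (p * (1 - p))) %*% X
  pll <- sum(y * eta - log1p(exp(eta))) +
    0.5 * determinant(I, logarithm = TRUE)$modulus
  list(coef = b, vcov = Iinv, iter = it, pll = as.numeric(pll))
}

# Penalized likelihood-ratio p-value for the group effect in a Firth fit.
firth_lrt <- function(X_full, X_null, y) {
  f1 <- firth_logit(X_full, y)
  f0 <- firth_logit(X_null, y)
  stat <- max(0, 2 * (f1$pll - f0$pll))
  df <- ncol(X_full) - ncol(X_null)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Binary-logistic occurrence model across groups
#'
#' Fits a logistic GLM of a binary per-animal outcome (e.g. "had at least
#' one GS") on the group factor and reports a Wald chi-square test for the
#' group effect plus Bonferroni-corrected pairwise contrasts. Groups in
#' which every animal is 0 (or 1) cause quasi-separation; the model is then
#' refit with Firth's penalized likelihood and flagged.
#'
#' @param table data.frame with `group` and binary `value` (0/1) columns.
#' @return list: `wald`, `df`, `p_value`, `separation` (logical),
#'   `pairwise` (comparison, p_unadj, p_adj), `coef`.
#' @export
occurrence_glm <- function(table) {
  check_group_table(table)
  if (!all(table$value %in% c(0, 1))) stop("occurrence outcome must be binary 0/1")
  g <- factor(table$group)
  y <- table$value
  X <- stats::model.matrix(~g)
  fit <- suppressWarnings(stats::glm(y ~ g, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 10) ||
    any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (sep) {
    ff <- firth_logit(X, y)
    beta <- ff$coef; V <- ff$vcov
  } else {
    beta <- stats::coef(fit); V <- stats::vcov(fit)
  }
  idx <- 2:ncol(X)  # group coefficients
  wald <- as.numeric(t(beta[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% beta[idx])
  df <- length(idx)
  p <- stats::pchisq(wald, df, lower.tail = FALSE)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(j) {
    sel <- g %in% pairs[, j]
    yy <- y[sel]
    gg <- droplevels(g[sel])
    if (length(unique(yy)) == 1) {
      p_un <- 1  # no outcome variation between the two groups
    } else {
      XX <- stats::model.matrix(~gg)
      f2 <- suppressWarnings(stats::glm(yy ~ gg, family = stats::binomial()))
      sep2 <- !f2$converged || any(abs(stats::coef(f2)) > 10)
      if (sep2) {
        p_un <- firth_lrt(XX, XX[, 1, drop = FALSE], yy)$p
      } else {
        z <- stats::coef(summary(f2))[2, "z value"]
        p_un <- 2 * stats::pnorm(-abs(z))
      }
    }
    data.frame(comparison = paste(pairs[1, j], pairs[2, j], sep = " - "),
               p_unadj = p_un, p_adj = min(1, p_un * m),
               stringsAsFactors = FALSE)
  }))
  list(wald = wald, df = df, p_value = p, separation = sep,
       pairwise = pw, coef = beta)
}

#' Per-band two-way ANOVA of EEG power
#'
#' Fits power ~ group x band (band as a 30-level factor, animals as
#' replicates) and reports Tukey-adjusted pairwise group contrasts within
#' each band, the layout used for 1-30 Hz total and relative power tables.
#'
#' @param band_table data.frame with `animal_id`, `group`, `band` (1-30)
#'   and `value` columns (one row per animal x band).
#' @return list with `anova` (two-way ANOVA table) and `pairwise_p`
#'   (data.frame: band x one column per group contrast, adjusted p).
#' @export
psd_twoway_anova <- function(band_table) {
  need <- c("group", "band", "value")
  if (!all(need %in% names(band_table)))
    stop("expected columns group, band, value")
  if (!setequal(unique(band_table$band), 1:30))
    stop("band table must contain bands 1-30")
  d <- data.frame(group = factor(band_table$group),
                  band = factor(band_table$band, levels = 1:30),
                  value = band_table$value)
  fit <- stats::lm(value ~ group * band, data = d)
  em <- emmeans::emmeans(fit, ~ group | band)
  prs <- summary(emmeans::contrast(em, method = "pairwise"), adjust = "tukey")
  wide <- stats::reshape(
    data.frame(band = as.integer(as.character(prs$band)),
               contrast = as.character(prs$contrast), p = prs$p.value),
    idvar = "band", timevar = "contrast", direction = "wide")
  names(wide) <- sub("^p\\.", "", names(wide))
  wide <- wide[order(wide$band), ]
  rownames(wide) <- NULL
  list(anova = stats::anova(fit), pairwise_p = wide)
}
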