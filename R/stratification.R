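#' Empirical ROC curve
#'
#' Builds the receiver operating characteristic of a continuous risk score
#' against a binary outcome, with higher scores treated as higher risk. One
#' point is emitted per candidate threshold: below the minimum score (all
#' positive calls), between each pair of adjacent distinct scores, and above
#' the maximum (no positive calls), so the curve runs from (sens = 1,
#' spec = 0) to (sens = 0, spec = 1).
#'
#' @param scores numeric risk scores.
#' @param outcomes logical (or 0/1) event indicators; both classes must be
#'   present.
#' @return object of class `roc_curve`: data.frame with columns `threshold`,
#'   `sensitivity`, `specificity`, and attribute `auc` (trapezoid rule).
#' @export
roc_curve <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  stopifnot(length(scores) == length(outcomes), !anyNA(scores), !anyNA(outcomes))
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate input: both outcome classes must be present")
  }
  u <- sort(unique(scores))
  # thresholds: below min, midpoints, above max; rule is score >= threshold
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(thr, function(t) sum(scores >= t & outcomes) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !outcomes) / n_neg, numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  # trapezoid AUC over (1 - specificity, sensitivity), sorted by FPR
  fpr <- 1 - out$specificity
  o <- order(fpr, out$sensitivity)
  auc <- sum(diff(fpr[o]) * (out$sensitivity[o][-1] + out$sensitivity[o][-nrow(out)]) / 2)
  structure(out, auc = auc, positive_label = TRUE, class = c("roc_curve", "data.frame"))
}

#' @rdname roc_curve
#' @param roc a `roc_curve` object.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Closest-to-corner optimal cutoff
#'
#' Selects the ROC threshold minimizing the Euclidean distance
#' \eqn{\sqrt{(1 - sens)^2 + (1 - spec)^2}} from the upper-left corner of the
#' unit square. Ties are broken toward the lower threshold, i.e. the more
#' sensitive rule. The returned rule classifies values at or above the
#' cutoff as the high stratum.
#'
#' @param roc a [roc_curve()].
#' @param variable optional name recorded on the rule.
#' @return object of class `strat_rule`: list with `variable`, `cutoff`,
#'   `direction` (`">="`), `distance`, `sensitivity`, `specificity`.
#' @export
optimal_cutoff_closest_to_corner <- function(roc, variable = NA_character_) {
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  best <- which(d <= min(d) + 1e-12)
  i <- best[which.min(roc$threshold[best])]
  structure(list(variable = variable, cutoff = roc$threshold[i],
                 direction = ">=", distance = d[i],
                 sensitivity = roc$sensitivity[i],
                 specificity = roc$specificity[i]),
            class = "strat_rule")
}

#' @export
print.strat_rule <- function(x, ...) {
  cat(sprintf("<strat_rule> %s %s %.4g (corner distance %.3f; sens %.3f, spec %.3f)\n",
              x$variable, x$direction, x$cutoff, x$distance,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square (no continuity correction), df = 1,
#' upper-tail p-value — the variant whose p-values match the reference
#' study's printed univariate comparisons.
#'
#' @param a,b,c,d cell counts: rows are strata, columns are died/survived.
#' @return list with `statistic`, `p_value`, `df`, `table`.
#' @export
pearson_chi2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(tab < 0) || sum(tab) == 0) validation_error("invalid 2x2 counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero margin")
  }
  # small expected counts only warn about the asymptotic approximation;
  # the uncorrected Pearson statistic is the intended report convention
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = 1L, table = tab)
}

#' Mann-Whitney U test
#'
#' Two-sided Wilcoxon rank-sum comparison of two independent samples. Exact
#' enumeration is used when both groups have at most 8 observations and no
#' ties; otherwise the normal approximation with tie correction (no
#' continuity correction, matching common statistical-package defaults).
#'
#' @param x,y numeric samples, both non-empty.
#' @return list with `statistic` (U for the first sample), `p_value`, `test`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) validation_error("empty group")
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       test = "mann_whitney")
}

#' Welch t-test
#'
#' Two-sided two-sample t-test with the Welch statistic and Satterthwaite
#' degrees of freedom.
#'
#' @param x,y numeric samples, each with at least 2 values.
#' @return list with `statistic`, `df`, `p_value`, `test`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) validation_error("each group needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(list(statistic = if (mean(x) == mean(y)) 0 else Inf,
                df = NA_real_,
                p_value = if (mean(x) == mean(y)) 1 else 0,
                test = "welch_t", degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), test = "welch_t")
}

#' Normality screen
#'
#' Routes a continuous variable to a parametric or rank test: returns
#' `"non_normal"` if either the Lilliefors-corrected Kolmogorov-Smirnov test
#' or the Shapiro-Wilk test rejects at `alpha`, or if the sample is
#' constant; `"normal"` otherwise.
#'
#' @param x numeric sample, n >= 3.
#' @param alpha rejection level.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_screen <- function(x, alpha = 0.05) {
  if (length(x) < 3) validation_error("normality screen needs n >= 3")
  if (stats::var(x) == 0) return("non_normal")
  p_sw <- stats::shapiro.test(if (length(x) > 5000) sample(x, 5000) else x)$p.value
  p_ks <- if (length(x) >= 4) nortest::lillie.test(x)$p.value else 1
  if (min(p_sw, p_ks) < alpha) "non_normal" else "normal"
}

#' Compare a continuous variable between two groups
#'
#' Applies the study's routing rule: Welch t-test when both groups pass
#' [normality_screen()], Mann-Whitney U otherwise. The chosen route is
#' recorded in the result.
#'
#' @param x,y numeric samples.
#' @return list as from the chosen test, plus `group_summaries`
#'   (mean +/- sd per group).
#' @export
univariate_compare <- function(x, y) {
  route <- if (length(x) >= 3 && length(y) >= 3 &&
               normality_screen(x) == "normal" &&
               normality_screen(y) == "normal") "welch_t" else "mann_whitney"
  res <- if (route == "welch_t") welch_t(x, y) else mann_whitney_u(x, y)
  res$group_summaries <- data.frame(
    group = c(1, 2), n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)))
  res
}

#' Stratified 30-day mortality table
#'
#' For each stratification rule, splits the cohort at the rule's cutoff and
#' tabulates stratum sizes, death counts, percentages (one decimal, half-up)
#' and the uncorrected Pearson chi-square p-value; an overall row is
#' included. Rules with an empty stratum are flagged and their p-value
#' omitted.
#'
#' @param summaries per-patient summary data.frame containing the rules'
#'   variables.
#' @param died logical vector of 30-day deaths aligned with `summaries`.
#' @param rules list of `strat_rule` objects.
#' @return data.frame with one row per stratum per rule plus an overall row.
#' @export
mortality_table <- function(summaries, died, rules) {
  died <- as.logical(died)
  rows <- list(data.frame(
    rule = "overall", stratum = "all", n = length(died),
    deaths = sum(died),
    pct = round_half_up(100 * sum(died) / length(died), 1),
    p_value = NA_real_))
  for (r in rules) {
    v <- summaries[[r$variable]]
    if (is.null(v)) validation_error(paste("unknown rule variable:", r$variable))
    hi <- v >= r$cutoff
    nlo <- sum(!hi); nhi <- sum(hi)
    dlo <- sum(died[!hi]); dhi <- sum(died[hi])
    p <- if (nlo == 0 || nhi == 0) NA_real_ else
      pearson_chi2(dlo, nlo - dlo, dhi, nhi - dhi)$p_value
    rows[[length(rows) + 1]] <- data.frame(
      rule = rep(r$variable, 2),
      stratum = paste(c("<", ">="), r$cutoff),
      n = c(nlo, nhi), deaths = c(dlo, dhi),
      pct = round_half_up(100 * c(dlo, dhi) / pmax(c(nlo, nhi), 1), 1),
      p_value = c(p, NA_real_))
  }
  do.call(rbind, rows)
}

#' Descriptive comparison table across strata
#'
#' Builds a two-group descriptive report for a stratification rule:
#' continuous variables as mean +/- sd with the routed test p-value
#' ([univariate_compare()]), binary variables as n (%) with the uncorrected
#' Pearson chi-square p-value.
#'
#' @param data patient-level data.frame (cohort columns plus summary columns).
#' @param group logical vector defining the second (high) group.
#' @param continuous,binary character vectors of column names.
#' @return data.frame with one row per variable: group summaries, test used,
#'   p-value.
#' @export
descriptive_table <- function(data, group,
                              continuous = character(),
                              binary = character()) {
  group <- as.logical(group)
  rows <- list()
  for (v in continuous) {
    x <- data[[v]][!group]; y <- data[[v]][group]
    res <- univariate_compare(x, y)
    rows[[v]] <- data.frame(
      variable = v, kind = "continuous",
      group1 = sprintf("%.1f ± %.1f", mean(x), stats::sd(x)),
      group2 = sprintf("%.1f ± %.1f", mean(y), stats::sd(y)),
      test = res$test, p_value = res$p_value)
  }
  for (v in binary) {
    x <- as.logical(data[[v]][!group]); y <- as.logical(data[[v]][group])
    p <- tryCatch(pearson_chi2(sum(x), sum(!x), sum(y), sum(!y))$p_value,
                  error = function(e) NA_real_)
    rows[[v]] <- data.frame(
      variable = v, kind = "binary",
      group1 = sprintf("%d (%.1f)", sum(x), round_half_up(100 * mean(x), 1)),
      group2 = sprintf("%d (%.1f)", sum(y), round_half_up(100 * mean(y), 1)),
      test = "chi_square", p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
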