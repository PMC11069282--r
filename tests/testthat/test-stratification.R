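test_that("ROC curve enumerates thresholds and reaches the corners", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(nrow(r), 5)
  expect_equal(roc_auc(r), 1)
  expect_true(any(r$sensitivity == 1 & r$specificity == 0))
  expect_true(any(r$sensitivity == 0 & r$specificity == 1))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "degenerate")
})

test_that("ROC AUC equals the Mann-Whitney concordance probability", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    scores <- round(rnorm(n), 1)  # ties included
    out <- rbinom(n, 1, 0.4)
    if (length(unique(out)) < 2) next
    w <- wilcox.test(scores[out == 1], scores[out == 0], exact = FALSE)
    concordance <- w$statistic / (sum(out) * sum(!out))
    expect_equal(roc_auc(roc_curve(scores, out)), unname(concordance),
                 tolerance = 1e-10)
  }
  # independent scores at large n hover around 0.5
  n <- 10000
  set.seed(7)
  auc <- roc_auc(roc_curve(rnorm(n), rbinom(n, 1, 0.15)))
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / (12 * n * 0.15 * 0.85)))
})

test_that("closest-to-corner cutoff agrees with brute force, ties go low", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(15:40, 1)
    scores <- round(runif(n, 0, 10), 1)
    out <- rbinom(n, 1, 0.4)
    if (length(unique(out)) < 2) next
    roc <- roc_curve(scores, out)
    rule <- optimal_cutoff_closest_to_corner(roc)
    d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
    expect_equal(rule$distance, min(d), tolerance = 1e-12)
    cand <- roc$threshold[d <= min(d) + 1e-12]
    expect_equal(rule$cutoff, min(cand))
  }
  rule <- optimal_cutoff_closest_to_corner(
    roc_curve(c(10, 20, 30, 40, 50), c(0, 0, 0, 1, 1)), "x")
  expect_equal(rule$distance, 0)
  expect_gt(rule$cutoff, 30)
  expect_lt(rule$cutoff, 40)
})

test_that("optimal cutoff partition is invariant under monotone transforms", {
  set.seed(3)
  scores <- runif(50, 50, 300)
  out <- rbinom(50, 1, plogis(scale(scores)))
  if (length(unique(out)) < 2) out[1:2] <- c(0, 1)
  r1 <- optimal_cutoff_closest_to_corner(roc_curve(scores, out))
  r2 <- optimal_cutoff_closest_to_corner(roc_curve(log(scores), out))
  expect_identical(scores >= r1$cutoff, log(scores) >= r2$cutoff)
})

test_that("Pearson chi-square matches the 2x2 closed form and null table", {
  cases <- list(c(4, 52, 13, 51), c(9, 8, 22, 81), c(3, 14, 4, 99),
                c(10, 10, 20, 20))
  for (cc in cases) {
    res <- pearson_chi2(cc[1], cc[2], cc[3], cc[4])
    a <- cc[1]; b <- cc[2]; c <- cc[3]; d <- cc[4]
    n <- sum(cc)
    stat_closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$statistic, stat_closed, tolerance = 1e-12)
    expect_equal(res$p_value, pchisq(stat_closed, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  nul <- pearson_chi2(10, 10, 20, 20)
  expect_equal(nul$statistic, 0)
  expect_equal(nul$p_value, 1)
  expect_error(pearson_chi2(0, 0, 5, 5), "degenerate")
})

test_that("Mann-Whitney exact p matches permutation enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)  # 2/20 arrangements as extreme, two-sided
  # independent enumeration over all C(6,3) label assignments
  vals <- c(1, 2, 3, 4, 5, 6)
  combos <- combn(6, 3)
  u_obs <- sum(outer(c(1, 2, 3), c(4, 5, 6), ">")) +
    0.5 * sum(outer(c(1, 2, 3), c(4, 5, 6), "=="))
  u_all <- apply(combos, 2, function(ix) {
    x <- vals[ix]; y <- vals[-ix]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  p_enum <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  expect_equal(res$p_value, p_enum)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_lt(mann_whitney_u(rnorm(200), rnorm(200) + 2)$p_value, 0.001)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Welch test matches the hand formula and degenerate conventions", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 100)
  res <- welch_t(x, y)
  se2 <- var(x) / 3 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 4)^2 / 3)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  expect_equal(welch_t(c(5, 5), c(5, 5))$p_value, 1)
  expect_equal(welch_t(c(5, 5), c(7, 7))$p_value, 0)
  # equal-variance large samples converge to the pooled t result
  set.seed(2)
  x <- rnorm(500); y <- rnorm(500, 0.1)
  expect_equal(welch_t(x, y)$p_value,
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-3)
})

test_that("normality screen separates normal from skewed samples", {
  set.seed(5)
  normal_calls <- replicate(20, normality_screen(rnorm(300)))
  expect_gte(mean(normal_calls == "normal"), 0.7)
  exp_calls <- replicate(20, normality_screen(rexp(300)))
  expect_true(all(exp_calls == "non_normal"))
  expect_equal(normality_screen(rep(3, 10)), "non_normal")
  expect_error(normality_screen(c(1, 2)), "n >= 3")
})

test_that("mortality table is sum-consistent and reproduces known strata", {
  # constructed cohort: 56/64 split with 4 vs 13 deaths
  summaries <- data.frame(est_pre_cv = c(rep(20, 56), rep(35, 64)))
  died <- c(rep(TRUE, 4), rep(FALSE, 52), rep(TRUE, 13), rep(FALSE, 51))
  rule <- structure(list(variable = "est_pre_cv", cutoff = 28.8,
                         direction = ">="), class = "strat_rule")
  tab <- mortality_table(summaries, died, list(rule))
  strata <- tab[tab$rule == "est_pre_cv", ]
  expect_equal(strata$n, c(56, 64))
  expect_equal(strata$deaths, c(4, 13))
  expect_equal(strata$pct, c(7.1, 20.3))
  expect_equal(strata$p_value[1], 0.039, tolerance = 1e-3)
  expect_equal(sum(strata$deaths), tab$deaths[tab$rule == "overall"])
})
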