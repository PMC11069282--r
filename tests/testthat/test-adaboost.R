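test_that("stratified split rounds per-class counts and is seeded", {
  died <- c(rep(FALSE, 103), rep(TRUE, 17))
  sp <- stratified_split(died, 0.75, seed = 1)
  expect_true(sum(!died[sp$train]) %in% c(77, 78))
  expect_true(sum(died[sp$train]) %in% c(12, 13))
  expect_setequal(c(sp$train, sp$test), seq_along(died))
  expect_identical(sp, stratified_split(died, 0.75, seed = 1))
  died8 <- rep(c(FALSE, TRUE), each = 8)
  sp8 <- stratified_split(died8, 0.75, seed = 2)
  expect_equal(sum(!died8[sp8$train]), 6)
  expect_equal(sum(died8[sp8$train]), 6)
  expect_error(stratified_split(c(TRUE, FALSE, FALSE)), "class")
})

test_that("min-max scaling maps train to [0,1], clips test, drops constants", {
  kind <- c(a = "continuous", b = "binary", c = "continuous")
  train <- data.frame(a = c(10, 20, 30), b = c(0, 1, 1), c = c(5, 5, 5))
  expect_warning(params <- fit_minmax(train, kind), "constant")
  expect_false("c" %in% params$keep)
  scaled <- apply_minmax(train, params)
  expect_equal(scaled[, "a"], c(0, 0.5, 1))
  expect_equal(scaled[, "b"], c(0, 1, 1))  # binary passes through
  test <- data.frame(a = c(35, 5), b = c(1, 0), c = c(9, 9))
  st <- apply_minmax(test, params)
  expect_equal(st[, "a"], c(1, 0))  # clipped
})

test_that("SMOTE balances classes with interpolated minority points", {
  set.seed(3)
  kind <- c(x1 = "continuous", x2 = "continuous", f = "binary")
  x <- cbind(x1 = runif(100), x2 = runif(100), f = rbinom(100, 1, 0.5))
  died <- c(rep(TRUE, 10), rep(FALSE, 90))
  out <- smote(x, died, kind, k_neighbors = 5, seed = 7)
  expect_equal(sum(out$died), 90)
  expect_equal(sum(out$synthetic), 80)
  expect_false(any(out$synthetic[1:100]))
  # synthetics lie within the minority bounding box (hull projection per axis)
  mins <- apply(x[1:10, 1:2], 2, min); maxs <- apply(x[1:10, 1:2], 2, max)
  syn <- out$x[out$synthetic, 1:2, drop = FALSE]
  expect_true(all(t(syn) >= mins - 1e-12 & t(syn) <= maxs + 1e-12))
  expect_true(all(out$x[out$synthetic, "f"] %in% c(0, 1)))
  # coincident minority points reproduce themselves (zero-length segments)
  pt <- c(x1 = 0.5, x2 = 0.5, f = 1)
  x2 <- rbind(pt, pt, cbind(x1 = runif(10), x2 = runif(10),
                            f = rbinom(10, 1, 0.5)))
  died2 <- c(TRUE, TRUE, rep(FALSE, 10))
  out2 <- smote(x2, died2, kind, seed = 1)
  expect_true(all(apply(out2$x[out2$synthetic, , drop = FALSE], 1,
                        function(r) all(r == pt))))
  expect_error(smote(x2[-1, ], died2[-1], kind, seed = 1), "minority")
})

test_that("FAS augmentation adds the right terms with deterministic names", {
  kind <- c(a = "continuous", b = "continuous", f = "binary", g = "binary")
  x <- cbind(a = c(0.2, 0.4), b = c(1, 0.5), f = c(1, 0), g = c(1, 1))
  aug <- fas_augment(x, kind)
  # p_cont squared + C(4,2) interactions on top of 4 raw
  expect_equal(ncol(aug$x), 4 + 2 + 6)
  expect_equal(aug$x[, "a^2"], x[, "a"]^2)
  expect_equal(aug$x[, "a*b"], x[, "a"] * x[, "b"])
  expect_equal(aug$x[, "f*g"], as.numeric(x[, "f"] & x[, "g"]))
  expect_equal(sum(aug$meta$provenance == "squared"), 2)
  expect_equal(sum(aug$meta$provenance == "interaction"), 6)
  expect_false(any(duplicated(aug$meta$name)))
  two <- fas_augment(x[, c("a", "b")], kind[c("a", "b")])
  expect_setequal(setdiff(colnames(two$x), c("a", "b")),
                  c("a^2", "b^2", "a*b"))
})

test_that("LASSO selection keeps signal features and always returns >= 1", {
  set.seed(17)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n); noise <- matrix(rnorm(3 * n), n)
  x <- cbind(x1 = x1, x2 = x2, n1 = noise[, 1], n2 = noise[, 2],
             n3 = noise[, 3])
  aug <- fas_augment(x, setNames(rep("continuous", 5), colnames(x)))
  y <- rbinom(n, 1, plogis(1.5 * x1 + 2 * x1 * x2)) == 1
  sel <- lasso_logistic_select(aug$x, y, seed = 5)
  expect_true(all(c("x1", "x1*x2") %in% sel))
  # full-shrinkage limit: fallback single feature
  sel_inf <- lasso_logistic_select(aug$x, y, seed = 5, lambda = c(50, 100))
  expect_equal(length(sel_inf), 1)
  expect_error(lasso_logistic_select(aug$x[1:12, ], y[1:12], cv_folds = 5),
               "cv_folds")
})

test_that("first-round stump equals brute-force exhaustive search", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(10:50, 1); p <- sample(2:5, 1)
    x <- matrix(round(rnorm(n * p), 2), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    died <- rbinom(n, 1, 0.4) == 1
    if (length(unique(died)) < 2) died[1:2] <- c(TRUE, FALSE)
    w <- runif(n); w <- w / sum(w)
    y <- ifelse(died, -1, 1)
    ours <- glycostrat:::find_best_stump(x, y, w)
    oracle <- brute_force_stump(x, y, w)
    expect_equal(ours$err, oracle$err, tolerance = 1e-12)
  }
})

test_that("AdaBoost separates 1-D separable data with a single stump", {
  x <- cbind(v = c(1, 2, 3, 10, 11, 12))
  died <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  model <- adaboost_train(x, died, L_rounds = 50)
  expect_equal(length(model$alphas), 1)
  expect_equal(adaboost_predict(model, x), ifelse(died, -1, 1),
               ignore_attr = TRUE)
})

test_that("ensemble equation holds: prediction is sign of weighted vote sum", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    died <- rbinom(n, 1, 0.5) == 1
    if (length(unique(died)) < 2) died[1:2] <- c(TRUE, FALSE)
    model <- adaboost_train(x, died, L_rounds = 15)
    expect_true(all(model$train_errors < 0.5))
    m <- adaboost_margin(model, x)
    manual <- rep(0, n)
    for (l in seq_along(model$alphas)) {
      s <- model$stumps[l, ]
      g <- ifelse(x[, s$index] <= s$threshold, s$polarity, -s$polarity)
      manual <- manual + model$alphas[l] * g
    }
    expect_equal(m, manual, tolerance = 1e-12)
    expect_equal(as.numeric(adaboost_predict(model, x)),
                 ifelse(manual < 0, -1, 1), ignore_attr = TRUE)
  }
})

test_that("exponential train loss is non-increasing over boosting rounds", {
  set.seed(31)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  died <- rbinom(n, 1, plogis(x[, 1] + 0.5 * x[, 2])) == 1
  if (length(unique(died)) < 2) died[1:2] <- c(TRUE, FALSE)
  model <- adaboost_train(x, died, L_rounds = 40)
  y <- ifelse(died, -1, 1)
  margin <- rep(0, n)
  losses <- vapply(seq_along(model$alphas), function(l) {
    s <- model$stumps[l, ]
    g <- ifelse(x[, s$index] <= s$threshold, s$polarity, -s$polarity)
    margin <<- margin + model$alphas[l] * g
    mean(exp(-y * margin))
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("FAS rescues AdaBoost on XOR-style interaction labels", {
  grid <- expand.grid(f1 = c(0, 1), f2 = c(0, 1))
  x <- grid[rep(1:4, each = 10), ]
  died <- xor(x$f1 == 1, x$f2 == 1)
  kind <- c(f1 = "binary", f2 = "binary")
  raw <- adaboost_train(as.matrix(x), died, L_rounds = 50)
  acc_raw <- mean((adaboost_predict(raw, as.matrix(x)) < 0) == died)
  expect_equal(acc_raw, 0.5, tolerance = 1e-12)
  aug <- fas_augment(as.matrix(x), kind)
  fas <- adaboost_train(aug$x, died, L_rounds = 50)
  acc_fas <- mean((adaboost_predict(fas, aug$x) < 0) == died)
  expect_lt(acc_raw, 1)  # raw features cannot express the interaction
  expect_equal(acc_fas, 1)
})

test_that("evaluation metrics satisfy their definitional identities", {
  # majority classifier on a 103/17 cohort
  died <- c(rep(TRUE, 17), rep(FALSE, 103))
  m <- evaluate_classifier(rep(FALSE, 120), died, risk_score = rep(0, 120))
  expect_equal(m$accuracy, 103 / 120)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 0.5)
  perfect <- evaluate_classifier(died, died, risk_score = as.numeric(died))
  expect_true(all(unlist(perfect[c("accuracy", "balanced_accuracy",
                                   "sensitivity", "specificity", "auc")]) == 1))
  set.seed(2)
  pred <- rbinom(120, 1, 0.5) == 1
  r <- evaluate_classifier(pred, died)
  expect_equal(r$balanced_accuracy, (r$sensitivity + r$specificity) / 2)
})

test_that("synthetic SMOTE rows never reach evaluation", {
  spec <- tiny_spec(n = 120, seed = 19)
  co <- generate_cohort(spec)
  s <- summarize_cohort(co)
  f <- build_ml_features(co, s)
  fit <- adaboost_fas_fit(f$x, f$kind, f$died, seed = 4, L_rounds = 20)
  # evaluation indexes only original rows: test rows are disjoint from train
  expect_length(intersect(fit$split$train, fit$split$test), 0)
  expect_lte(max(fit$split$test), nrow(f$x))
  # the synthetic flag covers exactly the SMOTE-added training rows
  expect_equal(sum(!fit$synthetic), length(fit$split$train))
})

test_that("model reliance is 1 for inert features, > 1 for the only signal", {
  # single-stump model driven entirely by feature `s`; `inert` plays no role
  set.seed(41)
  n <- 400
  x <- data.frame(s = runif(n), inert = runif(n))
  died <- x$s < 0.4
  # flip some labels so the baseline error is positive
  flip <- sample(n, 40)
  died[flip] <- !died[flip]
  kind <- c(s = "continuous", inert = "continuous")
  fit <- adaboost_fas_fit(x, kind, died, seed = 2, use_fas = FALSE,
                          use_smote = FALSE, L_rounds = 1)
  rel_inert <- model_reliance(fit, "inert", n_repeats = 500, seed = 3)
  expect_lt(abs(rel_inert$reliance - 1), 0.05)
  rel_s <- model_reliance(fit, "s", n_repeats = 100, seed = 3)
  expect_gt(rel_s$reliance, 1)
  expect_error(model_reliance(fit, "nope", 10, 1), "unknown")
})

test_that("full ML pipeline is deterministic under a fixed seed", {
  spec <- tiny_spec(n = 120, seed = 23)
  co <- generate_cohort(spec)
  f <- build_ml_features(co, summarize_cohort(co))
  m1 <- adaboost_fas_fit(f$x, f$kind, f$died, seed = 11, L_rounds = 25)
  m2 <- adaboost_fas_fit(f$x, f$kind, f$died, seed = 11, L_rounds = 25)
  expect_identical(m1$test_metrics, m2$test_metrics)
  expect_identical(m1$model$stumps, m2$model$stumps)
  expect_identical(m1$selected, m2$selected)
})
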