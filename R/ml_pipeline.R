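#' Assemble the ML feature table from a cohort
#'
#' Builds the 26-feature representation used by the mortality classifier:
#' demographics (age, sex), smoking habit, comorbidity flags, home-treatment
#' indicator columns, HbA1c, in-hospital mean and median glucose, the
#' in-hospital/pre-hospital mean glucose ratio, glycemic variability (SD)
#' and the Hirsch stability flag. Patient identifiers and length of stay are
#' deliberately excluded.
#'
#' @param cohort cohort data.frame (see [generate_cohort()]).
#' @param summaries matching output of [summarize_cohort()].
#' @return list with `x` (data.frame of features), `kind` (named vector,
#'   `"continuous"`/`"binary"`), `died` (logical).
#' @export
build_ml_features <- function(cohort, summaries) {
  stopifnot(identical(cohort$patient_id, summaries$patient_id))
  treat <- function(cat) as.numeric(cohort$home_treatment == cat)
  x <- data.frame(
    sglt2i_only = treat("sglt2i"),
    localized_malignancy = as.numeric(cohort$localized_malignancy),
    smoker = as.numeric(cohort$smoker),
    heart_failure = as.numeric(cohort$heart_failure),
    ckd = as.numeric(cohort$ckd),
    stroke_tia = as.numeric(cohort$stroke_tia),
    hemiplegia = as.numeric(cohort$hemiplegia),
    rheumatological_disease = as.numeric(cohort$rheumatological_disease),
    diet_only = treat("diet"),
    metformin_only = treat("metformin"),
    dpp4i_only = treat("dpp4i"),
    insulin_only = treat("insulin"),
    other_treatment = treat("other_combination"),
    hba1c = cohort$hba1c,
    in_mean = summaries$in_mean,
    in_median = summaries$in_median,
    ratio_in_pre = summaries$ratio_in_pre,
    in_sd = summaries$in_sd,
    hirsch_ok = as.numeric(summaries$hirsch_ok),
    pad = as.numeric(cohort$pad),
    dementia = as.numeric(cohort$dementia),
    t2dm_uncomplicated = as.numeric(cohort$t2dm_uncomplicated),
    t2dm_complicated = as.numeric(cohort$t2dm_complicated),
    age = cohort$age,
    hypertension = as.numeric(cohort$hypertension),
    male = as.numeric(cohort$male)
  )
  kind <- rep("binary", ncol(x))
  names(kind) <- names(x)
  kind[c("hba1c", "in_mean", "in_median", "ratio_in_pre", "in_sd", "age")] <-
    "continuous"
  list(x = x, kind = kind, died = as.logical(cohort$died_30d))
}

#' Fit the AdaBoost-FAS mortality classifier
#'
#' End-to-end training pipeline: stratified 75/25 split, min-max scaling
#' fitted on the training rows, SMOTE balancing of the training set (never
#' of the test set), squared/interaction feature augmentation, LASSO
#' selection of the augmented features, and discrete AdaBoost over decision
#' stumps on the selected features. Any stage can be switched off
#' (`use_fas`, `use_smote`) for ablation. All randomness derives from
#' `seed` through a fixed splitting scheme.
#'
#' @param x feature data.frame, `kind`, `died` as from
#'   [build_ml_features()].
#' @param kind named kind vector.
#' @param died logical outcome.
#' @param seed integer seed.
#' @param use_fas apply feature augmentation + LASSO selection.
#' @param use_smote balance training classes with SMOTE.
#' @param L_rounds boosting rounds.
#' @param k_neighbors SMOTE neighborhood size.
#' @param cv_folds folds for the LASSO penalty choice.
#' @param train_fraction training share of each class.
#' @return object of class `adaboost_fas`: the fitted ensemble plus frozen
#'   scaling parameters, selection, split indices, and test metrics.
#' @export
adaboost_fas_fit <- function(x, kind, died, seed = 1L,
                             use_fas = TRUE, use_smote = TRUE,
                             L_rounds = 100, k_neighbors = 5, cv_folds = 5,
                             train_fraction = 0.75) {
  died <- as.logical(died)
  split <- stratified_split(died, train_fraction, seed = child_seed(seed, 1))
  scaler <- fit_minmax(x[split$train, , drop = FALSE], kind)
  x_tr <- apply_minmax(x[split$train, , drop = FALSE], scaler)
  x_te <- apply_minmax(x[split$test, , drop = FALSE], scaler)
  y_tr <- died[split$train]
  synthetic <- rep(FALSE, length(y_tr))
  if (use_smote) {
    sm <- smote(x_tr, y_tr, scaler$kind, k_neighbors,
                seed = child_seed(seed, 2))
    x_tr <- sm$x; y_tr <- sm$died; synthetic <- sm$synthetic
  }
  selected <- NULL
  if (use_fas) {
    aug_tr <- fas_augment(x_tr, scaler$kind)
    cv_folds_eff <- min(cv_folds, floor(min(table(y_tr)) / 2))
    selected <- lasso_logistic_select(aug_tr$x, y_tr, cv_folds = cv_folds_eff,
                                      seed = child_seed(seed, 3))
    x_fit <- aug_tr$x[, selected, drop = FALSE]
  } else {
    x_fit <- x_tr
  }
  model <- adaboost_train(x_fit, y_tr, L_rounds = L_rounds)
  obj <- structure(list(
    model = model, scaler = scaler, selected = selected, use_fas = use_fas,
    split = split, seed = seed, synthetic = synthetic,
    x_raw = x, died = died), class = "adaboost_fas")
  obj$test_metrics <- evaluate_fit(obj, split$test)
  obj
}

# internal: scale + (re-)derive FAS features + subset to selection
prepare_features <- function(object, x_raw) {
  xs <- apply_minmax(x_raw, object$scaler)
  if (object$use_fas) {
    fas_augment(xs, object$scaler$kind)$x[, object$selected, drop = FALSE]
  } else {
    xs
  }
}

#' @rdname adaboost_fas_fit
#' @param object fitted `adaboost_fas`.
#' @param newdata raw (unscaled) feature data.frame; defaults to the held-out
#'   test rows.
#' @param ... unused.
#' @export
predict.adaboost_fas <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- object$x_raw[object$split$test, , drop = FALSE]
  }
  xf <- prepare_features(object, newdata)
  margin <- adaboost_margin(object$model, xf)
  list(margin = margin, died_pred = margin < 0)
}

# internal: metrics on a set of original-table row indices
evaluate_fit <- function(object, rows) {
  pr <- predict.adaboost_fas(object,
                             object$x_raw[rows, , drop = FALSE])
  evaluate_classifier(pr$died_pred, object$died[rows],
                      risk_score = -pr$margin)
}

#' Permutation model reliance
#'
#' Measures how much the classifier's test error grows when one base
#' feature is made uninformative: in each repeat the feature's column in the
#' held-out test set is replaced by a with-replacement resample of its own
#' test values, every derived (squared/interaction) feature of that parent
#' is recomputed, and the classification error re-evaluated. Reliance is the
#' mean perturbed error divided by the baseline error; a feature the model
#' never consults has reliance 1 in expectation.
#'
#' @param object fitted [adaboost_fas_fit()].
#' @param feature base-feature name to perturb.
#' @param n_repeats number of resampling repeats.
#' @param seed integer seed.
#' @return list: `feature`, `reliance`, `se`, `baseline_error`,
#'   `n_repeats`; `reliance` is `Inf` when the baseline error is zero but
#'   perturbation induces errors.
#' @export
model_reliance <- function(object, feature, n_repeats = 100, seed = NULL) {
  x_te <- object$x_raw[object$split$test, , drop = FALSE]
  if (!feature %in% names(x_te)) {
    validation_error(paste("unknown feature:", feature))
  }
  died_te <- object$died[object$split$test]
  base_err <- 1 - evaluate_fit(object, object$split$test)$accuracy
  with_seed(seed, {
    errs <- vapply(seq_len(n_repeats), function(r) {
      xp <- x_te
      xp[[feature]] <- sample(xp[[feature]], nrow(xp), replace = TRUE)
      pr <- predict.adaboost_fas(object, xp)
      mean(pr$died_pred != died_te)
    }, numeric(1))
    rel <- if (base_err > 0) mean(errs) / base_err else
      if (mean(errs) == 0) 1 else Inf
    list(feature = feature, reliance = rel,
         se = if (base_err > 0) stats::sd(errs) / sqrt(n_repeats) / base_err
              else NA_real_,
         baseline_error = base_err, n_repeats = n_repeats)
  })
}

#' Reference baseline classifiers
#'
#' Trains and evaluates the comparison models on the same split, scaling and
#' (where applicable) SMOTE balancing as [adaboost_fas_fit()]: `majority`
#' (always predicts survival), `dectree` and `dectree_fas` (CART with Gini
#' impurity, depth capped at `max_depth`), `lasso_fas` (logistic regression
#' on the LASSO-selected augmented features, 0.5 threshold), and
#' `adaboost` (no feature augmentation).
#'
#' @inheritParams adaboost_fas_fit
#' @param max_depth decision-tree depth cap.
#' @return named list of metric lists (one per model, as
#'   [evaluate_classifier()]), with the AdaBoost-FAS metrics included for
#'   reference under `adaboost_fas`.
#' @export
baseline_models <- function(x, kind, died, seed = 1L, L_rounds = 100,
                            k_neighbors = 5, cv_folds = 5, max_depth = 5) {
  died <- as.logical(died)
  fit_fas <- adaboost_fas_fit(x, kind, died, seed = seed, use_fas = TRUE,
                              L_rounds = L_rounds, k_neighbors = k_neighbors,
                              cv_folds = cv_folds)
  fit_raw <- adaboost_fas_fit(x, kind, died, seed = seed, use_fas = FALSE,
                              L_rounds = L_rounds, k_neighbors = k_neighbors)
  split <- fit_fas$split
  died_te <- died[split$test]
  out <- list(adaboost_fas = fit_fas$test_metrics,
              adaboost = fit_raw$test_metrics)

  out$majority <- evaluate_classifier(rep(FALSE, length(died_te)), died_te,
                                      risk_score = rep(0, length(died_te)))

  # shared preprocessed training data (scaled + SMOTE) from the FAS fit
  scaler <- fit_fas$scaler
  x_tr <- apply_minmax(x[split$train, , drop = FALSE], scaler)
  sm <- smote(x_tr, died[split$train], scaler$kind, k_neighbors,
              seed = child_seed(seed, 2))
  x_te <- apply_minmax(x[split$test, , drop = FALSE], scaler)
  tree_ctrl <- rpart::rpart.control(maxdepth = max_depth, minsplit = 4,
                                    minbucket = 2, cp = 0.001)
  fit_tree <- function(xtr, xte) {
    df <- as.data.frame(xtr)
    names(df) <- make.names(names(df))
    df$.y <- factor(sm$died, levels = c(FALSE, TRUE))
    tr <- rpart::rpart(.y ~ ., data = df, method = "class",
                       parms = list(split = "gini"), control = tree_ctrl)
    nd <- as.data.frame(xte)
    names(nd) <- make.names(colnames(xte))
    prob <- predict(tr, nd)[, "TRUE"]
    evaluate_classifier(prob > 0.5, died_te, risk_score = prob)
  }
  out$dectree <- fit_tree(sm$x, x_te)

  aug_tr <- fas_augment(sm$x, scaler$kind)
  aug_te <- fas_augment(x_te, scaler$kind)
  out$dectree_fas <- fit_tree(aug_tr$x, aug_te$x)

  sel <- fit_fas$selected
  df_tr <- as.data.frame(aug_tr$x[, sel, drop = FALSE])
  names(df_tr) <- make.names(sel, unique = TRUE)
  df_tr$.y <- sm$died
  glm_fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df_tr, family = stats::binomial()))
  df_te <- as.data.frame(aug_te$x[, sel, drop = FALSE])
  names(df_te) <- setdiff(names(df_tr), ".y")
  prob <- suppressWarnings(
    stats::predict(glm_fit, newdata = df_te, type = "response"))
  out$lasso_fas <- evaluate_classifier(prob > 0.5, died_te, risk_score = prob)
  out
}
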