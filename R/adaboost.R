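# ---- AdaBoost-FAS machine-learning arm -------------------------------------
#
# Label encoding throughout: -1 = deceased within 30 days, +1 = surviving.
# The ensemble is the classical discrete AdaBoost over decision stumps,
#   G(x) = sign( sum_l alpha_l g_l(x) ),
# with sign(0) resolved to +1 (the surviving / majority class).

#' Stratified train/test split
#'
#' Splits row indices per outcome class as close to `train_fraction` as
#' integer rounding allows, so both divisions keep a similar fraction of
#' surviving and deceased patients. Deterministic given `seed`.
#'
#' @param died logical outcome vector.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(died, train_fraction = 0.75, seed = NULL) {
  died <- as.logical(died)
  if (min(table(died)) < 2) validation_error("each class needs >= 2 members")
  with_seed(seed, {
    train <- unlist(lapply(c(FALSE, TRUE), function(cl) {
      idx <- which(died == cl)
      n_tr <- round(length(idx) * train_fraction)
      n_tr <- min(max(n_tr, 1), length(idx) - 1)
      sample(idx, n_tr)
    }))
    list(train = sort(train), test = sort(setdiff(seq_along(died), train)))
  })
}

#' Min-max scaling fitted on training data
#'
#' `fit_minmax()` learns per-feature minima and maxima of the continuous
#' features on the training rows; constant continuous features are dropped
#' with a warning. `apply_minmax()` maps continuous features through the
#' learned affine transform and clips to `[0, 1]` (test values outside the
#' training range saturate); binary features pass through unchanged.
#'
#' @param x data.frame or matrix of features.
#' @param kind named character vector, `"continuous"` or `"binary"` per
#'   feature.
#' @param params result of `fit_minmax()`.
#' @return `fit_minmax()`: list with `min`, `max`, `keep`, `kind`;
#'   `apply_minmax()`: numeric matrix of scaled features.
#' @export
fit_minmax <- function(x, kind) {
  x <- as.matrix(as.data.frame(lapply(as.data.frame(x), as.numeric)))
  stopifnot(all(colnames(x) %in% names(kind)))
  kind <- kind[colnames(x)]
  cont <- names(kind)[kind == "continuous"]
  mn <- apply(x[, cont, drop = FALSE], 2, min)
  mx <- apply(x[, cont, drop = FALSE], 2, max)
  dead <- cont[mx - mn == 0]
  if (length(dead) > 0) {
    warning("dropping constant continuous feature(s): ",
            paste(dead, collapse = ", "))
  }
  keep <- setdiff(colnames(x), dead)
  list(min = mn[setdiff(cont, dead)], max = mx[setdiff(cont, dead)],
       keep = keep, kind = kind[keep])
}

#' @rdname fit_minmax
#' @export
apply_minmax <- function(x, params) {
  x <- as.matrix(as.data.frame(lapply(as.data.frame(x), as.numeric)))
  x <- x[, params$keep, drop = FALSE]
  for (v in names(params$min)) {
    x[, v] <- pmin(pmax((x[, v] - params$min[v]) /
                          (params$max[v] - params$min[v]), 0), 1)
  }
  x
}

#' SMOTE minority-class oversampling
#'
#' Raises the minority-class count to the majority count by synthesizing
#' points on segments between minority samples and their k nearest minority
#' neighbors (Euclidean distance on the scaled features):
#' `x_new = x + u * (x_nn - x)`, `u ~ Uniform(0, 1)`. Binary features are
#' set by rounding the interpolated value at 0.5. Synthetic rows are flagged
#' so they can be excluded from any evaluation.
#'
#' @param x numeric matrix of scaled features.
#' @param died logical outcome vector; the rarer class is oversampled.
#' @param kind named kind vector as in [fit_minmax()].
#' @param k_neighbors neighborhood size; reduced (with a message) when the
#'   minority class has fewer than `k_neighbors + 1` members.
#' @param seed integer seed.
#' @return list with `x` (augmented matrix), `died`, `synthetic` (logical).
#' @export
smote <- function(x, died, kind, k_neighbors = 5, seed = NULL) {
  died <- as.logical(died)
  classes <- table(died)
  minority <- as.logical(names(classes)[which.min(classes)])
  n_min <- sum(died == minority)
  n_need <- max(classes) - n_min
  if (n_min < 2) validation_error("minority class needs >= 2 members")
  if (n_need == 0) {
    return(list(x = x, died = died, synthetic = rep(FALSE, length(died))))
  }
  k <- min(k_neighbors, n_min - 1)
  if (k < k_neighbors) message("SMOTE: k reduced to ", k)
  xm <- x[died == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- matrix(nn, ncol = n_min)  # k x n_min
  with_seed(seed, {
    base <- rep_len(seq_len(n_min), n_need)
    pick <- nn[cbind(sample(k, n_need, replace = TRUE), base)]
    u <- stats::runif(n_need)
    newx <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    bin <- names(kind)[kind == "binary"]
    bin <- intersect(bin, colnames(newx))
    newx[, bin] <- round(newx[, bin])
    list(x = rbind(x, newx),
         died = c(died, rep(minority, n_need)),
         synthetic = c(rep(FALSE, length(died)), rep(TRUE, n_need)))
  })
}

#' Feature augmentation: squared and interaction terms
#'
#' Adds one squared term per continuous feature (`X^2`) and one product term
#' per unordered pair of distinct features (`Y*Z`, continuous and binary
#' alike; for two binary flags the product is their logical AND). Names are
#' deterministic with parents in column order, so the same augmentation can
#' be re-derived on any table with the same raw columns.
#'
#' @param x numeric matrix of (scaled) raw features.
#' @param kind named kind vector.
#' @return list with `x` (augmented matrix) and `meta` (data.frame: name,
#'   provenance, parent1, parent2).
#' @export
fas_augment <- function(x, kind) {
  kind <- kind[colnames(x)]
  p <- ncol(x)
  meta <- data.frame(name = colnames(x), provenance = "raw",
                     parent1 = colnames(x), parent2 = NA_character_,
                     stringsAsFactors = FALSE)
  cols <- list(x)
  cont <- which(kind == "continuous")
  if (length(cont) > 0) {
    sq <- x[, cont, drop = FALSE]^2
    colnames(sq) <- paste0(colnames(x)[cont], "^2")
    cols[[length(cols) + 1]] <- sq
    meta <- rbind(meta, data.frame(name = colnames(sq), provenance = "squared",
                                   parent1 = colnames(x)[cont],
                                   parent2 = NA_character_))
  }
  if (p >= 2) {
    pairs <- utils::combn(p, 2)
    inter <- x[, pairs[1, ], drop = FALSE] * x[, pairs[2, ], drop = FALSE]
    colnames(inter) <- paste0(colnames(x)[pairs[1, ]], "*",
                              colnames(x)[pairs[2, ]])
    cols[[length(cols) + 1]] <- inter
    meta <- rbind(meta, data.frame(name = colnames(inter),
                                   provenance = "interaction",
                                   parent1 = colnames(x)[pairs[1, ]],
                                   parent2 = colnames(x)[pairs[2, ]]))
  }
  list(x = do.call(cbind, cols), meta = meta)
}

#' LASSO-logistic feature selection
#'
#' Fits an L1-penalized logistic regression over the augmented features
#' (via \pkg{glmnet}) with the penalty chosen by stratified k-fold
#' cross-validated binomial deviance, and returns the features with nonzero
#' coefficients at the selected penalty. If the selection is empty the
#' single feature with the largest absolute coefficient at the smallest
#' penalty on the path is returned, so at least one feature always survives.
#'
#' @param x numeric feature matrix (>= 2 columns).
#' @param died logical outcome.
#' @param cv_folds number of stratified folds.
#' @param seed integer seed for fold assignment.
#' @param lambda optional penalty grid passed to glmnet.
#' @return character vector of selected feature names.
#' @export
lasso_logistic_select <- function(x, died, cv_folds = 5, seed = NULL,
                                  lambda = NULL) {
  died <- as.logical(died)
  if (min(table(died)) < 2 * cv_folds) {
    validation_error("need >= 2 * cv_folds rows per class")
  }
  if (ncol(x) < 2) return(colnames(x))
  with_seed(seed, {
    foldid <- integer(length(died))
    for (cl in c(FALSE, TRUE)) {
      idx <- sample(which(died == cl))
      foldid[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
    cv <- glmnet::cv.glmnet(x, factor(died), family = "binomial",
                            foldid = foldid, lambda = lambda,
                            standardize = FALSE)
    co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
    sel <- names(co)[co != 0]
    if (length(sel) == 0) {
      co_min <- as.matrix(stats::coef(cv$glmnet.fit,
                                      s = min(cv$lambda)))[-1, 1]
      sel <- names(which.max(abs(co_min)))
    }
    sel
  })
}

#' Train a discrete AdaBoost ensemble of decision stumps
#'
#' Classical discrete AdaBoost: at each round the stump (feature, midpoint
#' threshold, polarity) minimizing the weighted 0-1 error is found by
#' exhaustive search over all features, all midpoints of adjacent distinct
#' training values, both polarities, and the two constant votes (a stump
#' whose leaves agree, as CART depth-1 trees permit — the ensemble's
#' intercept term); its vote weight is
#' \eqn{\alpha_l = \frac{1}{2}\log((1-\epsilon_l)/\epsilon_l)}; sample
#' weights are multiplied by \eqn{\exp(-\alpha_l y g_l(x))} and
#' renormalized. Training stops early when a stump separates the data
#' (\eqn{\epsilon_l = 0}; its weight is computed at a floored error) or when
#' no stump beats weighted error 0.5. Ties in weighted error are broken by
#' lower feature index, then lower threshold, then the polarity assigning
#' the surviving class to the low side, for full determinism.
#'
#' @param x numeric feature matrix.
#' @param died logical outcome (encoded internally as -1 deceased,
#'   +1 surviving).
#' @param L_rounds maximum number of boosting rounds.
#' @return object of class `adaboost`: list with `stumps` (data.frame:
#'   feature, index, threshold, polarity), `alphas`, `features`,
#'   `train_errors` (weighted error per round).
#' @export
adaboost_train <- function(x, died, L_rounds = 100) {
  y <- ifelse(as.logical(died), -1, 1)
  if (length(unique(y)) < 2) validation_error("both classes must be present")
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  errs <- numeric(0)
  for (l in seq_len(L_rounds)) {
    best <- find_best_stump(x, y, w)
    if (is.null(best) || best$err >= 0.5 - 1e-12) break
    eps <- max(best$err, 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    g <- stump_predict(best, x)
    stumps[[length(stumps) + 1]] <- best
    alphas <- c(alphas, alpha)
    errs <- c(errs, best$err)
    if (best$err <= 1e-12) break  # perfect separation: alpha capped above
    w <- w * exp(-alpha * y * g)
    w <- w / sum(w)
  }
  structure(list(
    stumps = do.call(rbind, lapply(stumps, function(s) data.frame(
      feature = s$feature, index = s$index, threshold = s$threshold,
      polarity = s$polarity))),
    alphas = alphas, features = colnames(x), train_errors = errs),
    class = "adaboost")
}

# internal: exhaustive weighted-error search over (feature, midpoint, polarity).
# polarity is the class (+1/-1) assigned to the "value <= threshold" side.
# The candidate set also contains the two constant votes (threshold = Inf),
# i.e. stumps whose leaves agree — these act as an intercept term, without
# which vote ensembles cannot represent some interaction-driven labelings
# (their decision boundary would have an intercept tied to the vote weights).
find_best_stump <- function(x, y, w) {
  best <- NULL
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xv <- x[o, j]
    wy <- (w * (y == -1))[o]   # weight of deceased
    wp <- (w * (y == 1))[o]    # weight of surviving
    distinct <- which(diff(xv) > 0)
    if (length(distinct) == 0) next
    thr <- (xv[distinct] + xv[distinct + 1]) / 2
    cum_neg <- cumsum(wy)[distinct]  # deceased weight on low side
    cum_pos <- cumsum(wp)[distinct]  # surviving weight on low side
    tot_neg <- sum(wy); tot_pos <- sum(wp)
    # polarity +1: low side called surviving -> errors: deceased on low side
    #              + surviving on high side
    err_p <- cum_neg + (tot_pos - cum_pos)
    # polarity -1: low side called deceased
    err_m <- cum_pos + (tot_neg - cum_neg)
    for (pol in c(1, -1)) {
      e <- if (pol == 1) err_p else err_m
      i <- which.min(e)
      if (is.null(best) || e[i] < best$err - 1e-15) {
        best <- list(feature = colnames(x)[j], index = j,
                     threshold = thr[i], polarity = pol, err = e[i])
      }
    }
  }
  # constant votes, considered last (threshold Inf sorts after all midpoints)
  for (pol in c(1, -1)) {
    err <- sum(w[y != pol])
    if (is.null(best) || err < best$err - 1e-15) {
      best <- list(feature = "(constant)", index = 1L, threshold = Inf,
                   polarity = pol, err = err)
    }
  }
  best
}

# internal: stump vote in {-1, +1}
stump_predict <- function(stump, x) {
  ifelse(x[, stump$index] <= stump$threshold, stump$polarity, -stump$polarity)
}

#' Ensemble margin and class prediction
#'
#' `adaboost_margin()` returns the real-valued vote sum
#' \eqn{\sum_l \alpha_l g_l(x)}; `adaboost_predict()` returns its sign with
#' zero resolved to +1 (surviving, the majority class) — each such
#' resolution is counted in attribute `n_zero_margin`.
#'
#' @param model an [adaboost_train()] fit.
#' @param x feature matrix with the model's feature columns.
#' @return numeric margins, or a vector in `{-1, +1}`.
#' @export
adaboost_margin <- function(model, x) {
  x <- x[, model$features, drop = FALSE]
  m <- numeric(nrow(x))
  if (is.null(model$stumps)) return(m)
  for (l in seq_along(model$alphas)) {
    s <- as.list(model$stumps[l, ])
    m <- m + model$alphas[l] * stump_predict(s, x)
  }
  m
}

#' @rdname adaboost_margin
#' @export
adaboost_predict <- function(model, x) {
  m <- adaboost_margin(model, x)
  out <- ifelse(m < 0, -1, 1)
  structure(out, n_zero_margin = sum(m == 0))
}

#' Classification metrics
#'
#' Confusion-matrix metrics with the deceased class as the positive class:
#' sensitivity is recall on deceased patients, specificity recall on
#' survivors, and balanced accuracy their mean. AUC is computed from a
#' real-valued risk score (higher = more likely deceased) when supplied;
#' with a single-class truth it is reported as `NA`.
#'
#' @param pred_died logical or -1/+1 predictions (-1 or `TRUE` = deceased).
#' @param died logical truth.
#' @param risk_score optional continuous score for AUC.
#' @return list: `accuracy`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `confusion` (tp/fn/fp/tn on the deceased class).
#' @export
evaluate_classifier <- function(pred_died, died, risk_score = NULL) {
  if (is.numeric(pred_died)) pred_died <- pred_died < 0
  died <- as.logical(died)
  tp <- sum(pred_died & died); fn <- sum(!pred_died & died)
  fp <- sum(pred_died & !died); tn <- sum(!pred_died & !died)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (!is.null(risk_score) && length(unique(died)) == 2) {
    roc_auc(roc_curve(risk_score, died))
  } else NA_real_
  list(accuracy = (tp + tn) / length(died),
       balanced_accuracy = mean(c(sens, spec)),
       sensitivity = sens, specificity = spec, auc = auc,
       confusion = c(tp = tp, fn = fn, fp = fp, tn = tn))
}
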