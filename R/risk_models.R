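#' Multivariable logistic regression for 30-day mortality
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) returning
#' per-covariate odds ratios with Wald 95% confidence intervals
#' `exp(beta +/- 1.96 SE)` and Wald p-values, unpenalized to mirror
#' conventional clinical-statistics output. Near-separation (any
#' `|beta| > 15`) is flagged in the metadata rather than corrected, since
#' the extreme odds ratios it produces are themselves informative.
#'
#' @param design data.frame or matrix of covariates (no intercept column).
#' @param outcome logical or 0/1 event vector.
#' @return object of class `regression_result`: data.frame with columns
#'   `term`, `coefficient`, `OR`, `ci95_low`, `ci95_high`, `se`, `p_value`;
#'   attributes `n`, `events`, `converged`, `iterations`, `separation`,
#'   `model`.
#' @export
logistic_fit <- function(design, outcome) {
  design <- as.data.frame(design)
  outcome <- as.numeric(as.logical(outcome))
  if (nrow(design) != length(outcome)) validation_error("length mismatch")
  if (nrow(design) <= ncol(design)) {
    validation_error("need more observations than covariates")
  }
  const <- vapply(design, function(v) stats::var(as.numeric(v)) == 0, logical(1))
  if (any(const)) {
    validation_error(paste("constant covariate column(s):",
                           paste(names(design)[const], collapse = ", ")))
  }
  x <- as.matrix(data.frame(lapply(design, as.numeric)))
  if (qr(cbind(1, x))$rank < ncol(x) + 1) {
    stop("rank-deficient design: collinear columns among ",
         paste(colnames(x), collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm(outcome ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  sm <- summary(fit)$coefficients
  est <- sm[-1, 1]; se <- sm[-1, 2]; p <- sm[-1, 4]
  res <- data.frame(
    term = colnames(x), coefficient = unname(est), OR = exp(unname(est)),
    ci95_low = exp(unname(est - 1.96 * se)),
    ci95_high = exp(unname(est + 1.96 * se)),
    se = unname(se), p_value = unname(p))
  structure(res, class = c("regression_result", "data.frame"),
            n = nrow(x), events = sum(outcome),
            converged = fit$converged, iterations = fit$iter,
            separation = any(abs(est) > 15), model = "logistic")
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling (via
#' [survival::coxph()]); follow-up is administratively censored at
#' `horizon` days. Returns hazard ratios with Wald 95% CIs and p-values in
#' the same shape as [logistic_fit()].
#'
#' @param time follow-up times in days (> 0).
#' @param event logical or 0/1 event indicator; at least one event required.
#' @param design data.frame or matrix of covariates.
#' @param horizon administrative censoring time, days.
#' @return `regression_result` (column `OR` holds the hazard ratio); the
#'   fitted `coxph` object is attached as attribute `fit` for downstream
#'   curve prediction.
#' @export
cox_fit <- function(time, event, design, horizon = 30) {
  design <- as.data.frame(design)
  event <- as.logical(event)
  if (any(time <= 0)) validation_error("times must be positive", "time")
  if (!any(event)) validation_error("at least one event required", "event")
  event_c <- event & time <= horizon
  time_c <- pmin(time, horizon)
  x <- as.matrix(data.frame(lapply(design, as.numeric)))
  df <- data.frame(time = time_c, status = as.numeric(event_c))
  fit <- survival::coxph(
    survival::Surv(time, status) ~ x, data = df, ties = "efron",
    control = survival::coxph.control(eps = 1e-10, iter.max = 100))
  sm <- summary(fit)$coefficients
  est <- sm[, "coef"]; se <- sm[, "se(coef)"]; p <- sm[, "Pr(>|z|)"]
  res <- data.frame(
    term = colnames(x), coefficient = unname(est), OR = exp(unname(est)),
    ci95_low = exp(unname(est - 1.96 * se)),
    ci95_high = exp(unname(est + 1.96 * se)),
    se = unname(se), p_value = unname(p))
  structure(res, class = c("regression_result", "data.frame"),
            n = nrow(x), events = sum(event_c),
            converged = fit$iter < 100,
            iterations = fit$iter, separation = any(abs(est) > 15),
            model = "cox", fit = fit, data = df, x = x)
}

#' Adjusted survival curves per stratum
#'
#' Predicted survival from a fitted Cox model for each level of a binary
#' stratification flag, with all other covariates held at their cohort
#' means (Breslow-type baseline via [survival::survfit()]).
#'
#' @param cox a `regression_result` from [cox_fit()].
#' @param strata_term name of the binary covariate defining the strata.
#' @return data.frame with columns `stratum`, `time`, `survival`.
#' @export
survival_curves <- function(cox, strata_term) {
  fit <- attr(cox, "fit")
  x <- attr(cox, "x")
  if (!strata_term %in% colnames(x)) {
    validation_error(paste("strata term not in design:", strata_term))
  }
  means <- colMeans(x)
  newx <- rbind(low = means, high = means)
  newx[, strata_term] <- c(0, 1)
  nd <- data.frame(x = I(newx))
  sf <- survival::survfit(fit, newdata = nd)
  surv <- as.matrix(sf$surv)
  out <- do.call(rbind, lapply(1:2, function(j) data.frame(
    stratum = c("below_cutoff", "at_or_above_cutoff")[j],
    time = c(0, sf$time), survival = c(1, surv[, j]))))
  rownames(out) <- NULL
  out
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result: %s> n=%d events=%d%s\n",
              attr(x, "model"), attr(x, "n"), attr(x, "events"),
              if (isTRUE(attr(x, "separation"))) " [near-separation]" else ""))
  print.data.frame(cbind(x[, c("term", "coefficient")],
                         round(x[, c("OR", "ci95_low", "ci95_high", "p_value")], 4)),
                   row.names = FALSE)
  invisible(x)
}
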