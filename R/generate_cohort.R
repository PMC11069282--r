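# inverse-CDF draw from a normal truncated to [lo, hi]; vectorized and
# deterministic in the number of uniforms consumed
rtruncnorm_inv <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

# lognormal parameters matching a target arithmetic mean and sd
lognormal_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Calibrate the outcome-model intercept
#'
#' Finds the intercept `b` such that the mean of
#' `plogis(b + X %*% effect_log_odds)` over the supplied covariate sample
#' equals `target_rate`, by monotone root finding. With all effects zero the
#' result is the closed-form logit of the target.
#'
#' @param effect_log_odds named numeric vector of log-odds coefficients
#'   (may be empty).
#' @param covariates data.frame or matrix containing a column for every name
#'   in `effect_log_odds`.
#' @param target_rate desired mean event probability, in (0, 1).
#' @return intercept on the log-odds scale; mean predicted probability
#'   matches `target_rate` to within 1e-6.
#' @export
calibrate_intercept <- function(effect_log_odds, covariates, target_rate) {
  if (!is.numeric(target_rate) || target_rate <= 0 || target_rate >= 1) {
    validation_error("target_rate must be in (0, 1)", "target_rate")
  }
  if (length(effect_log_odds) == 0) {
    return(stats::qlogis(target_rate))
  }
  miss <- setdiff(names(effect_log_odds), colnames(covariates))
  if (length(miss) > 0) {
    validation_error(paste("covariates missing:", paste(miss, collapse = ", ")),
                     "covariates")
  }
  x <- as.matrix(as.data.frame(covariates)[, names(effect_log_odds),
                                           drop = FALSE])
  storage.mode(x) <- "double"
  eta <- drop(x %*% effect_log_odds)
  if (any(!is.finite(eta))) {
    stop("calibration error: non-finite linear predictor (degenerate covariates)")
  }
  f <- function(b) mean(stats::plogis(b + eta)) - target_rate
  # mean(plogis) is strictly increasing in b with limits 0 and 1
  stats::uniroot(f, lower = -60, upper = 60, tol = 1e-10,
                 extendInt = "upX")$root
}

#' Generate a synthetic hospital cohort
#'
#' Draws a cohort of T2DM admissions according to a [cohort_spec()]:
#' demographics and comorbidities from independent marginals, admission HbA1c
#' from a truncated normal, the pre-admission mean glucose via
#' [hba1c_to_mean_glucose()], a per-patient in-hospital mean as the
#' pre-admission mean times a ratio draw, and an in-hospital glucose series
#' (four slots per day: breakfast, lunch, dinner, bedtime; one value per slot
#' for every day of stay) as truncated-support lognormal noise whose
#' arithmetic mean and coefficient of variation match the patient's latent
#' in-hospital mean and dispersion draw. The 30-day death indicator follows
#' a logistic model over the planted `effect_log_odds`, with the intercept
#' calibrated by [calibrate_intercept()] so the expected mortality equals
#' `spec$mortality_rate`. Length of stay is lognormal with outcome-specific
#' moments, rounded to whole days, floored at 2 and capped at 60; for
#' deceased patients the stay is the day of death.
#'
#' The result is a pure function of the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per patient: `patient_id`, `age`, `male`,
#'   `smoker`, one logical column per comorbidity flag (plus
#'   `t2dm_uncomplicated` / `t2dm_complicated`), `home_treatment`, `hba1c`,
#'   `length_of_stay`, `died_30d`, a `glucose` list-column of mg/dl series,
#'   a `glucose_slot` list-column of slot labels, and `n_measurements`.
#'   Latent generating values are attached as attribute `latent`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- as.integer(spec$n_patients)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  age <- rtruncnorm_inv(n, spec$age_mean, spec$age_sd, lo = 18)
  male <- stats::runif(n) < spec$male_prob
  smoker <- stats::runif(n) < spec$smoker_prob
  flags <- sapply(spec$comorbidity_prevalences,
                  function(p) stats::runif(n) < p)
  flags <- matrix(flags, nrow = n,
                  dimnames = list(NULL, names(spec$comorbidity_prevalences)))
  t2dm_complicated <- stats::runif(n) < spec$t2dm_complicated_prob
  home_treatment <- sample(names(spec$treatment_distribution), n,
                           replace = TRUE, prob = spec$treatment_distribution)
  hba1c <- rtruncnorm_inv(n, spec$hba1c_mean, spec$hba1c_sd, lo = 4, hi = 15)
  pre_mean <- hba1c_to_mean_glucose(hba1c)
  ratio <- rtruncnorm_inv(n, spec$ratio_mean, spec$ratio_sd, lo = 0.3)
  cv <- stats::runif(n, spec$within_patient_cv_range[1],
                     spec$within_patient_cv_range[2]) / 100
  in_mean_latent <- pre_mean * ratio
  in_sd_latent <- cv * in_mean_latent

  covars <- data.frame(
    age = age, male = as.numeric(male), smoker = as.numeric(smoker),
    hba1c = hba1c, in_sd = in_sd_latent, in_cv = 100 * cv,
    est_pre_cv = 100 * in_sd_latent / pre_mean,
    t2dm_complicated = as.numeric(t2dm_complicated),
    t2dm_uncomplicated = as.numeric(!t2dm_complicated)
  )
  covars <- cbind(covars, as.data.frame(flags))
  beta <- spec$effect_log_odds
  unknown <- setdiff(names(beta), names(covars))
  if (length(unknown) > 0) {
    validation_error(paste("unknown effect covariates:",
                           paste(unknown, collapse = ", ")),
                     "effect_log_odds")
  }
  intercept <- calibrate_intercept(beta, covars, spec$mortality_rate)
  eta <- if (length(beta) == 0) rep(0, n) else
    drop(as.matrix(covars[, names(beta), drop = FALSE]) %*% beta)
  died <- stats::runif(n) < stats::plogis(intercept + eta)

  stay <- numeric(n)
  ps <- lognormal_params(spec$stay_mean_survivor, spec$stay_sd_survivor)
  pd <- lognormal_params(spec$stay_mean_deceased, spec$stay_sd_deceased)
  stay_draw <- stats::rlnorm(n, ps$meanlog, ps$sdlog)
  stay_draw_d <- stats::rlnorm(n, pd$meanlog, pd$sdlog)
  stay <- ifelse(died, stay_draw_d, stay_draw)
  stay <- pmin(pmax(round(stay), 2), 60)

  slots <- c("breakfast", "lunch", "dinner", "bedtime")
  n_obs <- 4L * as.integer(stay)
  lp <- lognormal_params(in_mean_latent, in_sd_latent + 1e-12)
  all_vals <- stats::rlnorm(sum(n_obs),
                            rep(lp$meanlog, n_obs), rep(lp$sdlog, n_obs))
  idx <- rep(seq_len(n), n_obs)
  glucose <- split(all_vals, idx)
  names(glucose) <- NULL
  glucose_slot <- lapply(n_obs, function(k) rep(slots, length.out = k))

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age, male = male, smoker = smoker,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(flags),
                  t2dm_uncomplicated = !t2dm_complicated,
                  t2dm_complicated = t2dm_complicated)
  cohort$home_treatment <- home_treatment
  cohort$hba1c <- hba1c
  cohort$length_of_stay <- stay
  cohort$died_30d <- died
  cohort$glucose <- glucose
  cohort$glucose_slot <- glucose_slot
  cohort$n_measurements <- n_obs
  attr(cohort, "latent") <- data.frame(
    pre_mean_glucose = pre_mean, ratio = ratio, cv = 100 * cv,
    in_mean = in_mean_latent, in_sd = in_sd_latent,
    intercept = intercept, eta = eta
  )
  cohort
}

#' Write / read a cohort as CSV
#'
#' The wide format serializes each glucose series as a semicolon-delimited
#' field (`glucose`) with matching `glucose_slot` labels; a schema version
#' header comment is written first. `read_cohort_csv()` round-trips the
#' result.
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param path file path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  out$glucose <- vapply(cohort$glucose,
                        function(v) paste(format(v, digits = 12, trim = TRUE),
                                          collapse = ";"), character(1))
  out$glucose_slot <- vapply(cohort$glucose_slot, paste, character(1),
                             collapse = ";")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# glycostrat cohort schema v1", con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("glucose" %in% names(df)) {
    df$glucose <- lapply(strsplit(as.character(df$glucose), ";", fixed = TRUE),
                         as.numeric)
  }
  if ("glucose_slot" %in% names(df)) {
    df$glucose_slot <- strsplit(as.character(df$glucose_slot), ";",
                                fixed = TRUE)
  }
  logical_cols <- c("male", "smoker", "died_30d", "t2dm_uncomplicated",
                    "t2dm_complicated",
                    intersect(names(charlson_weights), names(df)))
  for (cl in intersect(logical_cols, names(df))) df[[cl]] <- as.logical(df[[cl]])
  df
}
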