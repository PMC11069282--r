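#' Specification of a synthetic hospital cohort
#'
#' Bundles the marginal distributions and planted outcome effects that drive
#' [generate_cohort()]. Defaults emulate a published pilot cohort of 120
#' hospitalized T2DM patients: age 78.4 +/- 8.9 years, HbA1c 7.0 +/- 1.6%,
#' in-hospital/pre-hospital mean glucose ratio 1.12 +/- 0.27, 30-day
#' mortality 17/120, survivor/deceased stays 15.5/9.3 days, and the stated
#' comorbidity and home-treatment prevalences.
#'
#' @param n_patients number of patients (>= 2).
#' @param mortality_rate target expected 30-day mortality, in (0, 1).
#' @param age_mean,age_sd age distribution, years (truncated at >= 18).
#' @param hba1c_mean,hba1c_sd admission HbA1c distribution, percent
#'   (truncated to `[4, 15]`).
#' @param male_prob,smoker_prob probabilities of male sex and smoking habit.
#' @param comorbidity_prevalences named probabilities for the comorbidity
#'   flags; names must be valid Charlson flags (the two diabetes terms are
#'   handled via `t2dm_complicated_prob`).
#' @param t2dm_complicated_prob probability that the (universal) T2DM carries
#'   chronic complications; the complement is flagged uncomplicated.
#' @param treatment_distribution named probabilities over home antidiabetic
#'   treatment categories; must sum to 1 within 1e-9.
#' @param ratio_mean,ratio_sd distribution of the in-hospital over
#'   pre-hospital mean glucose ratio (truncated at >= 0.3).
#' @param within_patient_cv_range two-element percent interval; each
#'   patient's dispersion of in-hospital glucose around their own mean is a
#'   uniform draw from this range.
#' @param stay_mean_survivor,stay_sd_survivor,stay_mean_deceased,stay_sd_deceased
#'   length-of-stay moments, days; lognormal, rounded to whole days >= 2.
#'   For deceased patients the stay is the day of death.
#' @param effect_log_odds named log-odds coefficients planted on the 30-day
#'   death model. Valid names: any comorbidity flag, `male`, `smoker`, `age`
#'   (per year), `hba1c` (per percent), `in_sd` (per mg/dl), `in_cv`,
#'   `est_pre_cv` (per percent). Glycemic covariates use the patient's
#'   generating (latent) values. The intercept is calibrated so the expected
#'   mortality equals `mortality_rate`.
#' @param seed integer seed; the generated cohort is a pure function of the
#'   spec including the seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 120,
                        mortality_rate = 17 / 120,
                        age_mean = 78.4, age_sd = 8.9,
                        hba1c_mean = 7.0, hba1c_sd = 1.6,
                        male_prob = 0.60,
                        smoker_prob = 0.367,
                        comorbidity_prevalences = c(
                          hypertension = 0.767,
                          ischemic_heart_disease = 0.233,
                          heart_failure = 0.133,
                          ckd = 0.267,
                          stroke_tia = 0.158,
                          pad = 0.117,
                          copd = 0.258,
                          mild_hepatopathy = 0.017,
                          severe_hepatopathy = 0.008,
                          peptic_ulcer = 0,
                          aids = 0,
                          hemiplegia = 0.042,
                          localized_malignancy = 0.225,
                          metastatic_malignancy = 0.058,
                          dementia = 0.258,
                          rheumatological_disease = 0.017
                        ),
                        t2dm_complicated_prob = 0.533,
                        treatment_distribution = c(
                          diet = 14, metformin = 31, sulphonylureas = 2,
                          dpp4i = 4, glp1ra = 1, insulin = 26, sglt2i = 5,
                          other_combination = 37
                        ) / 120,
                        ratio_mean = 1.12, ratio_sd = 0.27,
                        within_patient_cv_range = c(12, 45),
                        stay_mean_survivor = 15.5, stay_sd_survivor = 12.6,
                        stay_mean_deceased = 9.3, stay_sd_deceased = 4.6,
                        effect_log_odds = c(
                          hemiplegia = 2.5, dementia = 1.4, male = 0.9,
                          in_sd = 0.02
                        ),
                        seed = 1L) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  chk_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      validation_error("probabilities must lie in [0, 1]", field)
    }
  }
  if (!is.numeric(spec$n_patients) || spec$n_patients < 2) {
    validation_error("n_patients must be >= 2", "n_patients")
  }
  if (spec$mortality_rate <= 0 || spec$mortality_rate >= 1) {
    validation_error("mortality_rate must be in (0, 1)", "mortality_rate")
  }
  chk_prob(spec$comorbidity_prevalences, "comorbidity_prevalences")
  chk_prob(spec$male_prob, "male_prob")
  chk_prob(spec$smoker_prob, "smoker_prob")
  chk_prob(spec$t2dm_complicated_prob, "t2dm_complicated_prob")
  unknown <- setdiff(names(spec$comorbidity_prevalences),
                     c(names(charlson_weights), non_charlson_flags))
  if (length(unknown) > 0) {
    validation_error(paste("unknown comorbidity names:",
                           paste(unknown, collapse = ", ")),
                     "comorbidity_prevalences")
  }
  chk_prob(spec$treatment_distribution, "treatment_distribution")
  if (abs(sum(spec$treatment_distribution) - 1) > 1e-9) {
    validation_error("treatment_distribution must sum to 1",
                     "treatment_distribution")
  }
  if (length(spec$within_patient_cv_range) != 2 ||
      any(spec$within_patient_cv_range <= 0) ||
      diff(spec$within_patient_cv_range) < 0) {
    validation_error("within_patient_cv_range must be a positive interval",
                     "within_patient_cv_range")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_patients, "patients, target mortality",
      format(x$mortality_rate, digits = 3), "\n")
  cat("  age", x$age_mean, "+/-", x$age_sd, "| HbA1c", x$hba1c_mean, "+/-",
      x$hba1c_sd, "| seed", x$seed, "\n")
  if (length(x$effect_log_odds)) {
    cat("  planted log-odds:",
        paste(names(x$effect_log_odds), format(x$effect_log_odds),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
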