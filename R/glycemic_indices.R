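#' Convert HbA1c to estimated average glucose
#'
#' Linear ADAG (A1c-Derived Average Glucose) regression map
#' \deqn{eAG = 28.7 \times HbA1c - 46.7}
#' giving the mean blood glucose (mg/dl) corresponding to a glycated
#' hemoglobin percentage. Used here to estimate each patient's pre-admission
#' mean glucose from the HbA1c drawn within 48 h of admission. The slope and
#' intercept are exposed so alternative linear calibrations can be swapped in.
#'
#' @param hba1c glycated hemoglobin, percent; must lie in `[4, 15]`.
#' @param slope,intercept coefficients of the linear map (mg/dl per percent
#'   and mg/dl).
#' @return estimated average glucose in mg/dl.
#' @examples
#' hba1c_to_mean_glucose(7.0)  # 154.2
#' @export
hba1c_to_mean_glucose <- function(hba1c, slope = 28.7, intercept = -46.7) {
  if (any(!is.finite(hba1c)) || any(hba1c < 4) || any(hba1c > 15)) {
    validation_error("hba1c must be finite and within [4, 15] percent", "hba1c")
  }
  slope * hba1c + intercept
}

#' Per-patient glycemic summary
#'
#' Summarizes an in-hospital pre-prandial glucose series against the
#' HbA1c-derived pre-admission mean:
#' \itemize{
#'   \item `in_mean`, `in_median`, `in_sd`: arithmetic mean, sample median and
#'     sample standard deviation (n-1 denominator) of the series, mg/dl.
#'     `in_sd` is the "glycemic variability" index.
#'   \item `in_cv`: in-hospital coefficient of variation,
#'     `100 * in_sd / in_mean`, percent.
#'   \item `est_pre_cv`: estimated pre-hospitalization glycemic CV,
#'     `100 * in_sd / pre_mean_glucose` — the in-hospital variability scaled
#'     by the pre-admission mean instead of the in-hospital mean.
#'   \item `ratio_in_pre`: in-hospital over pre-admission mean glucose.
#'   \item `hirsch_ok`: Hirsch stability rule, `TRUE` when the SD does not
#'     exceed one third of the in-hospital mean (`3 * in_sd <= in_mean`).
#' }
#'
#' `est_pre_cv` equals `in_cv` exactly when the in-hospital mean equals the
#' pre-admission mean (`ratio_in_pre == 1`).
#'
#' @param glucose_series numeric vector of glucose values, mg/dl; length >= 2.
#' @param hba1c admission HbA1c, percent.
#' @param conversion function mapping HbA1c to pre-admission mean glucose;
#'   defaults to [hba1c_to_mean_glucose()].
#' @return a one-row data.frame with columns `pre_mean_glucose`, `in_mean`,
#'   `in_median`, `in_sd`, `in_cv`, `est_pre_cv`, `ratio_in_pre`, `hirsch_ok`,
#'   `n_measurements`.
#' @examples
#' summarize_glycemia(c(120, 140, 160, 180), hba1c = 7.0)
#' @export
summarize_glycemia <- function(glucose_series, hba1c,
                               conversion = hba1c_to_mean_glucose) {
  if (length(glucose_series) < 2) {
    validation_error("glucose_series must contain at least 2 values",
                     "glucose_series")
  }
  if (any(!is.finite(glucose_series)) || any(glucose_series <= 0)) {
    validation_error("glucose values must be finite and positive",
                     "glucose_series")
  }
  pre_mean <- conversion(hba1c)
  in_mean <- mean(glucose_series)
  in_sd <- stats::sd(glucose_series)
  data.frame(
    pre_mean_glucose = pre_mean,
    in_mean = in_mean,
    in_median = stats::median(glucose_series),
    in_sd = in_sd,
    in_cv = 100 * in_sd / in_mean,
    est_pre_cv = 100 * in_sd / pre_mean,
    ratio_in_pre = in_mean / pre_mean,
    hirsch_ok = 3 * in_sd <= in_mean,
    n_measurements = length(glucose_series)
  )
}

# Original Charlson weights, keyed by the comorbidity flag names used in the
# cohort schema. Exactly one of the two diabetes flags may be set.
charlson_weights <- c(
  ischemic_heart_disease = 1L,
  heart_failure = 1L,
  pad = 1L,
  stroke_tia = 1L,
  dementia = 1L,
  copd = 1L,
  rheumatological_disease = 1L,
  mild_hepatopathy = 1L,
  t2dm_uncomplicated = 1L,
  peptic_ulcer = 1L,
  hemiplegia = 2L,
  ckd = 2L,
  t2dm_complicated = 2L,
  localized_malignancy = 2L,
  severe_hepatopathy = 3L,
  metastatic_malignancy = 6L,
  aids = 6L
)

# comorbidity flags tracked in the cohort that do not enter the Charlson score
non_charlson_flags <- "hypertension"

#' Charlson Comorbidity Index
#'
#' Weighted sum of comorbid conditions using the original 1987 weights
#' (1 point: myocardial/ischemic heart disease, heart failure, peripheral
#' arterial disease, stroke/TIA, dementia, COPD, rheumatological disease,
#' mild hepatopathy, uncomplicated diabetes, peptic ulcer; 2 points:
#' hemiplegia, moderate/severe CKD, diabetes with chronic complications,
#' localized or hematological malignancy; 3: severe hepatopathy; 6:
#' metastatic malignancy, AIDS). At most one of the two diabetes terms may
#' contribute. With `age_adjusted = TRUE` one point is added per decade of
#' age at or above 50, capped at 4 (age >= 80).
#'
#' @param flags named logical vector or list of comorbidity indicators; names
#'   must be a subset of `names(glycostrat:::charlson_weights)`.
#' @param age age in years; required when `age_adjusted = TRUE`.
#' @param age_adjusted logical; add the age component.
#' @return integer score.
#' @examples
#' charlson_index(c(dementia = TRUE, metastatic_malignancy = TRUE,
#'                  t2dm_complicated = TRUE))  # 9
#' @export
charlson_index <- function(flags, age = NULL, age_adjusted = FALSE) {
  flags <- unlist(flags)
  # cohort comorbidities that carry no Charlson weight are ignored
  unknown <- setdiff(names(flags),
                     c(names(charlson_weights), non_charlson_flags))
  if (length(unknown) > 0) {
    validation_error(paste("unknown comorbidity flags:",
                           paste(unknown, collapse = ", ")), "flags")
  }
  flags <- flags[names(flags) %in% names(charlson_weights)]
  if (isTRUE(flags["t2dm_uncomplicated"]) && isTRUE(flags["t2dm_complicated"])) {
    validation_error("at most one diabetes flag may be set", "flags")
  }
  score <- sum(charlson_weights[names(flags)[as.logical(flags)]])
  if (age_adjusted) {
    if (is.null(age)) validation_error("age required when age_adjusted", "age")
    score <- score + min(max(floor((age - 40) / 10), 0), 4)
  }
  as.integer(score)
}

#' Apply the cohort inclusion filters
#'
#' Inclusion requires at least 12 consecutive pre-prandial glucose
#' determinations, a hospitalization of at least 48 hours (2 days), and an
#' admission HbA1c measurement. Each excluded record is labeled with the
#' first failing rule, checked in that order.
#'
#' @param cohort a cohort data.frame as produced by [generate_cohort()] (long
#'   glucose series attached as attribute or counted via `n_measurements`).
#'   Must contain columns `patient_id`, `hba1c`, `length_of_stay` and either
#'   `n_measurements` or a `glucose` list-column.
#' @return list with elements `included` (data.frame) and `excluded`
#'   (data.frame with column `reason`).
#' @export
apply_inclusion_filters <- function(cohort) {
  n_meas <- if ("n_measurements" %in% names(cohort)) {
    cohort$n_measurements
  } else if ("glucose" %in% names(cohort)) {
    vapply(cohort$glucose, length, integer(1))
  } else {
    validation_error("cohort must carry n_measurements or a glucose list-column")
  }
  reason <- rep(NA_character_, nrow(cohort))
  reason[is.na(reason) & n_meas < 12] <- "insufficient_glucose_measurements"
  reason[is.na(reason) & cohort$length_of_stay < 2] <- "stay_under_48h"
  reason[is.na(reason) & (is.na(cohort$hba1c))] <- "missing_hba1c"
  keep <- is.na(reason)
  excluded <- cohort[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(included = cohort[keep, , drop = FALSE], excluded = excluded)
}

#' Summarize glycemia for a whole cohort
#'
#' Applies [summarize_glycemia()] to every patient and appends the Charlson
#' Comorbidity Index, returning one row per patient keyed by `patient_id`.
#'
#' @param cohort cohort data.frame with a `glucose` list-column (see
#'   [generate_cohort()]).
#' @param age_adjusted_cci logical passed to [charlson_index()].
#' @return data.frame of per-patient summaries.
#' @export
summarize_cohort <- function(cohort, age_adjusted_cci = FALSE) {
  stopifnot("glucose" %in% names(cohort))
  flag_cols <- intersect(names(charlson_weights), names(cohort))
  out <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    s <- summarize_glycemia(cohort$glucose[[i]], cohort$hba1c[i])
    s$cci <- charlson_index(
      as.logical(cohort[i, flag_cols]) |> stats::setNames(flag_cols),
      age = cohort$age[i], age_adjusted = age_adjusted_cci)
    s
  }))
  cbind(patient_id = cohort$patient_id, out)
}
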