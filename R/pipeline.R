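# Printed counts from the reference pilot study of 120 hospitalized T2DM
# patients, used as fixtures by verify_reference_tables(): stratum sizes and
# 30-day death counts for the three glycemic stratifications, and the
# deceased/survivor comorbidity counts behind the univariate comparisons.
reference_counts <- list(
  n_total = 120L, deaths_total = 17L,
  strata = data.frame(
    rule = c("in_sd", "in_cv", "est_pre_cv"),
    cutoff = c(42.55, 25.8, 28.8),
    n_low = c(54L, 48L, 56L), n_high = c(66L, 72L, 64L),
    deaths_low = c(4L, 4L, 4L), deaths_high = c(13L, 13L, 13L),
    printed_pct_low = c(7.4, 8.3, 7.1), printed_pct_high = c(19.7, 18.1, 20.3)
  ),
  univariate = data.frame(
    variable = c("dementia", "metastatic_malignancy", "hemiplegia"),
    deceased_with = c(9L, 3L, 4L), deceased_total = 17L,
    survivor_with = c(22L, 4L, 1L), survivor_total = 103L,
    printed_pct_deceased = c(52.9, 17.6, 23.5),
    printed_p = c(0.006, 0.025, NA)  # hemiplegia printed only as p < 0.001
  )
)

#' Recompute the reference study's printed mortality tables
#'
#' From the printed stratum and comorbidity counts of the reference cohort
#' (120 patients, 17 deaths), recomputes the subgroup mortality percentages
#' and uncorrected Pearson chi-square p-values and compares them with the
#' printed values at the printed precision. This checks that the package's
#' tabulation and test conventions (half-up one-decimal rounding,
#' chi-square without continuity correction) reproduce the published
#' report exactly.
#'
#' @return data.frame with columns `quantity`, `computed`, `printed`,
#'   `match`; attribute `pass` is `TRUE` when all comparisons match.
#' @export
verify_reference_tables <- function() {
  rc <- reference_counts
  rows <- list()
  add <- function(quantity, computed, printed, digits) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, computed = computed, printed = printed,
      match = is.na(printed) | round_half_up(computed, digits) == printed)
  }
  s <- rc$strata
  for (i in seq_len(nrow(s))) {
    add(paste0(s$rule[i], "_pct_low"),
        100 * s$deaths_low[i] / s$n_low[i], s$printed_pct_low[i], 1)
    add(paste0(s$rule[i], "_pct_high"),
        100 * s$deaths_high[i] / s$n_high[i], s$printed_pct_high[i], 1)
  }
  # only the estimated pre-hospital CV stratification reaches significance
  p_epcv <- pearson_chi2(4, 52, 13, 51)$p_value
  add("est_pre_cv_chi2_p", p_epcv, 0.039, 3)
  u <- rc$univariate
  for (i in seq_len(nrow(u))) {
    a <- u$deceased_with[i]; b <- u$deceased_total[i] - a
    c <- u$survivor_with[i]; d <- u$survivor_total[i] - c
    add(paste0(u$variable[i], "_pct_deceased"),
        100 * a / u$deceased_total[i], u$printed_pct_deceased[i], 1)
    add(paste0(u$variable[i], "_chi2_p"),
        pearson_chi2(a, b, c, d)$p_value, u$printed_p[i], 3)
  }
  out <- do.call(rbind, rows)
  structure(out, pass = all(out$match))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> filter -> indices -> stratify -> fit -> ml on a
#' synthetic cohort (or a cohort CSV), writing every report to
#' `output_dir`: the included/excluded cohort, per-patient summaries,
#' descriptive and mortality stratification tables, logistic and Cox
#' results per glycemic rule, adjusted survival curves, ML metrics and
#' model-reliance values, plus a manifest recording seeds and an output
#' hash. Cutoffs are either fixed (defaults: SD 42.55 mg/dl, in-hospital CV
#' 25.8%, estimated pre-hospital CV 28.8%) or re-derived from the data by
#' the closest-to-corner ROC rule.
#'
#' @param spec a [cohort_spec()], or `NULL` when `cohort_csv` is given.
#' @param cohort_csv optional path to a cohort CSV (see
#'   [read_cohort_csv()]).
#' @param output_dir directory for the report bundle (created if missing).
#' @param cutoffs named numeric vector `c(in_sd=, in_cv=, est_pre_cv=)`, or
#'   `"derive"` to select cutoffs from the data via
#'   [optimal_cutoff_closest_to_corner()].
#' @param seed global seed; stage seeds are derived via [child_seed()].
#' @param L_rounds boosting rounds for the ML stage.
#' @param reliance_features base features for model reliance (`NULL` skips).
#' @param n_repeats reliance repeats.
#' @return invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(spec = NULL, cohort_csv = NULL,
                         output_dir = tempfile("glycostrat_run_"),
                         cutoffs = c(in_sd = 42.55, in_cv = 25.8,
                                     est_pre_cv = 28.8),
                         seed = 1L, L_rounds = 100,
                         reliance_features = c("in_sd", "dementia",
                                               "hemiplegia"),
                         n_repeats = 50) {
  if (is.null(spec) == is.null(cohort_csv)) {
    validation_error("exactly one of spec / cohort_csv must be given")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (!is.null(spec)) {
    spec$seed <- child_seed(seed, 10)
    generate_cohort(spec)
  } else {
    df <- read_cohort_csv(cohort_csv)
    required <- c("patient_id", "hba1c", "length_of_stay", "died_30d",
                  "glucose")
    miss <- setdiff(required, names(df))
    if (length(miss) > 0) {
      validation_error(paste("cohort CSV missing columns:",
                             paste(miss, collapse = ", ")))
    }
    df
  }

  filt <- apply_inclusion_filters(cohort)
  write_cohort_csv(filt$included, file.path(output_dir, "cohort_included.csv"))
  utils::write.csv(
    filt$excluded[, setdiff(names(filt$excluded),
                            c("glucose", "glucose_slot"))],
    file.path(output_dir, "cohort_excluded.csv"), row.names = FALSE)
  cohort <- filt$included
  if (nrow(cohort) < 10) stop("stage indices: fewer than 10 included patients")

  summaries <- summarize_cohort(cohort)
  utils::write.csv(summaries, file.path(output_dir, "summaries.csv"),
                   row.names = FALSE)

  rule_vars <- c("in_sd", "in_cv", "est_pre_cv")
  rules <- if (identical(cutoffs, "derive")) {
    lapply(rule_vars, function(v) {
      optimal_cutoff_closest_to_corner(
        roc_curve(summaries[[v]], cohort$died_30d), variable = v)
    })
  } else {
    lapply(rule_vars, function(v) {
      structure(list(variable = v, cutoff = unname(cutoffs[v]),
                     direction = ">="), class = "strat_rule")
    })
  }

  mort <- mortality_table(summaries, cohort$died_30d, rules)
  utils::write.csv(mort, file.path(output_dir, "mortality_table.csv"),
                   row.names = FALSE)

  desc_vars_cont <- c("age", "length_of_stay", "hba1c")
  desc_vars_bin <- intersect(
    c("male", "smoker", "hypertension", "copd", "hemiplegia", "dementia",
      "metastatic_malignancy"), names(cohort))
  data_full <- cbind(cohort[, setdiff(names(cohort),
                                      c("glucose", "glucose_slot"))],
                     summaries[, -1])
  desc <- descriptive_table(data_full, cohort$died_30d,
                            continuous = c(desc_vars_cont, "in_mean", "in_sd",
                                           "in_cv", "est_pre_cv"),
                            binary = desc_vars_bin)
  utils::write.csv(desc, file.path(output_dir, "descriptive_table.csv"),
                   row.names = FALSE)

  design_base <- data.frame(
    age = cohort$age, male = as.numeric(cohort$male),
    length_of_stay = cohort$length_of_stay,
    hemiplegia = as.numeric(cohort$hemiplegia),
    metastatic_malignancy = as.numeric(cohort$metastatic_malignancy),
    dementia = as.numeric(cohort$dementia))
  logistic <- list(); cox <- list(); curves <- list()
  time <- pmax(cohort$length_of_stay, 1)
  for (r in rules) {
    flag <- as.numeric(summaries[[r$variable]] >= r$cutoff)
    if (stats::var(flag) == 0) next
    nm <- paste0(r$variable, "_high")
    design <- cbind(design_base, stats::setNames(data.frame(flag), nm))
    logistic[[r$variable]] <- logistic_fit(design, cohort$died_30d)
    utils::write.csv(
      as.data.frame(logistic[[r$variable]]),
      file.path(output_dir, paste0("logistic_", r$variable, ".csv")),
      row.names = FALSE)
    cci <- summaries$cci
    cx <- cox_fit(time, cohort$died_30d,
                  data.frame(age = cohort$age, male = as.numeric(cohort$male),
                             cci = cci,
                             stats::setNames(data.frame(flag), nm)))
    cox[[r$variable]] <- cx
    curves[[r$variable]] <- survival_curves(cx, nm)
    utils::write.csv(curves[[r$variable]],
                     file.path(output_dir,
                               paste0("survival_", r$variable, ".csv")),
                     row.names = FALSE)
  }

  feats <- build_ml_features(cohort, summaries)
  ml_fit <- adaboost_fas_fit(feats$x, feats$kind, feats$died,
                             seed = child_seed(seed, 20),
                             L_rounds = L_rounds)
  reliance <- NULL
  if (!is.null(reliance_features)) {
    reliance <- do.call(rbind, lapply(reliance_features, function(f) {
      r <- model_reliance(ml_fit, f, n_repeats = n_repeats,
                          seed = child_seed(seed, 21))
      data.frame(feature = f, reliance = r$reliance, se = r$se)
    }))
    utils::write.csv(reliance, file.path(output_dir, "reliance.csv"),
                     row.names = FALSE)
  }
  metrics <- ml_fit$test_metrics
  jsonlite::write_json(metrics[c("accuracy", "balanced_accuracy",
                                 "sensitivity", "specificity", "auc")],
                       file.path(output_dir, "ml_metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(setdiff(list.files(output_dir), "manifest.json"))
  hashes <- unname(tools::md5sum(file.path(output_dir, files)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("glycostrat")),
    seed = seed,
    stage_seeds = list(simulate = child_seed(seed, 10),
                       ml = child_seed(seed, 20),
                       reliance = child_seed(seed, 21)),
    cutoffs = if (identical(cutoffs, "derive")) "derived-from-data"
              else as.list(cutoffs),
    n_included = nrow(cohort),
    files = stats::setNames(as.list(unname(hashes)), files))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, excluded = filt$excluded,
                 summaries = summaries, rules = rules,
                 mortality_table = mort, descriptive_table = desc,
                 logistic = logistic, cox = cox, curves = curves,
                 ml = ml_fit, metrics = metrics, reliance = reliance,
                 manifest = manifest, output_dir = output_dir))
}
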