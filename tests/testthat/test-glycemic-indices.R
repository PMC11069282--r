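test_that("HbA1c converts to estimated average glucose linearly", {
  expect_equal(hba1c_to_mean_glucose(7.0), 154.2)
  expect_equal(hba1c_to_mean_glucose(5.0), 96.8)
  expect_equal(hba1c_to_mean_glucose(7.0) - hba1c_to_mean_glucose(6.0), 28.7)
  expect_error(hba1c_to_mean_glucose(3.5), "hba1c")
  expect_error(hba1c_to_mean_glucose(16), "hba1c")
})

test_that("glycemic summary matches hand computation", {
  s <- summarize_glycemia(c(120, 140, 160, 180), hba1c = 7.0)
  expect_equal(s$in_mean, 150)
  expect_equal(s$in_median, 150)
  expect_equal(s$in_sd, sd(c(120, 140, 160, 180)))  # n-1 denominator
  expect_equal(s$in_cv, 100 * s$in_sd / 150, tolerance = 1e-12)
  expect_equal(s$est_pre_cv, 100 * s$in_sd / 154.2, tolerance = 1e-12)
  expect_equal(s$ratio_in_pre, 150 / 154.2, tolerance = 1e-12)
  expect_equal(s$n_measurements, 4)

  s0 <- summarize_glycemia(rep(100, 4), hba1c = 7.0)
  expect_equal(s0$in_sd, 0)
  expect_equal(s0$in_cv, 0)
  expect_equal(s0$est_pre_cv, 0)
  expect_true(s0$hirsch_ok)
  expect_error(summarize_glycemia(100, 7), "glucose_series")
})

test_that("CV is scale-invariant, est_pre_cv scales, order is irrelevant", {
  g <- c(95, 140, 210, 130, 160, 180)
  s1 <- summarize_glycemia(g, 7.5)
  s2 <- summarize_glycemia(2 * g, 7.5)
  expect_equal(s2$in_cv, s1$in_cv, tolerance = 1e-12)
  expect_equal(s2$est_pre_cv, 2 * s1$est_pre_cv, tolerance = 1e-12)
  s3 <- summarize_glycemia(sample(g), 7.5)
  expect_equal(s3, s1)
  # identity: est_pre_cv == in_cv when the two means coincide
  hb <- (mean(g) + 46.7) / 28.7
  s4 <- summarize_glycemia(g, hb)
  expect_equal(s4$ratio_in_pre, 1, tolerance = 1e-12)
  expect_equal(s4$est_pre_cv, s4$in_cv, tolerance = 1e-12)
})

test_that("Hirsch rule flags series whose SD exceeds a third of the mean", {
  stable <- c(150, 160, 170, 160)
  expect_true(summarize_glycemia(stable, 7)$hirsch_ok)
  wild <- c(60, 300, 70, 320, 65, 310)
  expect_false(summarize_glycemia(wild, 7)$hirsch_ok)
})

test_that("Charlson index follows the original weight table", {
  expect_equal(charlson_index(c(hypertension = TRUE)), 0L)
  expect_equal(charlson_index(c(t2dm_uncomplicated = TRUE)), 1L)
  expect_equal(charlson_index(c(t2dm_complicated = TRUE)), 2L)
  expect_equal(charlson_index(c(metastatic_malignancy = TRUE, dementia = TRUE,
                                t2dm_complicated = TRUE)), 9L)
  expect_error(charlson_index(c(t2dm_uncomplicated = TRUE,
                                t2dm_complicated = TRUE)), "diabetes")
  expect_error(charlson_index(c(gout = TRUE)), "unknown")
  # age adjustment: +1 per decade from 50, capped at 4
  expect_equal(charlson_index(c(), age = 45, age_adjusted = TRUE), 0L)
  expect_equal(charlson_index(c(dementia = TRUE), age = 78,
                              age_adjusted = TRUE), 1L + 3L)
  expect_equal(charlson_index(c(), age = 95, age_adjusted = TRUE), 4L)
})

test_that("Charlson index is monotone under adding any flag", {
  base_flags <- c(dementia = TRUE, ckd = TRUE)
  base <- charlson_index(base_flags)
  for (f in setdiff(names(glycostrat:::charlson_weights),
                    c(names(base_flags), "t2dm_complicated"))) {
    flags <- c(base_flags, stats::setNames(TRUE, f))
    expect_gte(charlson_index(flags), base)
  }
})

test_that("inclusion filters exclude by the first failing rule in order", {
  co <- generate_cohort(tiny_spec(n = 6, seed = 4))
  co$glucose[[1]] <- co$glucose[[1]][1:11]          # too few measurements
  co$n_measurements[1] <- 11L
  co$length_of_stay[2] <- 1                          # short stay
  co$hba1c[3] <- NA                                  # missing HbA1c
  # record 4 fails both rules 1 and 2: labeled with the first
  co$glucose[[4]] <- co$glucose[[4]][1:5]
  co$n_measurements[4] <- 5L
  co$length_of_stay[4] <- 1
  filt <- apply_inclusion_filters(co)
  expect_equal(nrow(filt$included), 2)
  expect_equal(filt$excluded$reason,
               c("insufficient_glucose_measurements", "stay_under_48h",
                 "missing_hba1c", "insufficient_glucose_measurements"))
})
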