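Package: glycostrat
Title: Glycemic Variability Indices and 30-Day Mortality Stratification in
    Hospitalized Type 2 Diabetes Patients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline relating pre-hospital and in-hospital glycemic
    indexes to 30-day in-hospital all-cause mortality in hospitalized type 2
    diabetes patients. Computes per-patient glycemic summaries from bedside
    glucose series, including the estimated pre-hospitalization glycemic
    coefficient of variation (in-hospital glucose standard deviation divided
    by the HbA1c-derived pre-admission mean glucose), derives ROC-based
    closest-to-corner cutoffs, stratifies the cohort with univariate
    statistics, fits multivariable logistic and Cox models, and trains an
    AdaBoost decision-stump classifier with SMOTE class balancing, squared
    and interaction feature augmentation with LASSO selection, and
    permutation model-reliance analysis. A seeded synthetic-cohort generator
    with plantable outcome effects makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    rpart,
    nortest,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
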