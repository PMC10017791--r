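fake_results <- function(tp, tn, fp, fn) {
  tibble::tibble(
    sample_id = "s1",
    posterior_tumor = c(rep(0.9, tp), rep(0.1, tn), rep(0.9, fp),
                        rep(0.1, fn)),
    predicted = c(rep("tumor", tp), rep("normal", tn), rep("tumor", fp),
                  rep("normal", fn)),
    truth = c(rep("tumor", tp), rep("normal", tn), rep("normal", fp),
              rep("tumor", fn)))
}

test_that("evaluation reproduces hand-computed rates", {
  rep_ <- evaluate_classification(fake_results(9, 8, 2, 1))
  expect_equal(unname(rep_$confusion), c(9, 8, 2, 1))
  expect_equal(rep_$correct_rate, 0.85)
  expect_equal(rep_$sensitivity, 0.9)
  expect_equal(rep_$specificity, 0.8)
  expect_equal(unname(rep_$per_class), c(0.8, 0.9))

  all_good <- evaluate_classification(fake_results(5, 5, 0, 0))
  expect_equal(all_good$correct_rate, 1)
  expect_equal(all_good$sensitivity, 1)
  expect_equal(all_good$specificity, 1)

  expect_error(evaluate_classification(fake_results(0, 0, 0, 0)), "no ")
})

test_that("per-sample fractions and posterior summaries are computed per sample", {
  res <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 4),
    posterior_tumor = c(0.99, 0.97, 0.6, 0.2, 0.01, 0.02, 0.3, 0.96),
    predicted = c("tumor", "tumor", "tumor", "normal",
                  "normal", "normal", "normal", "tumor"),
    truth = c(rep("tumor", 4), rep("normal", 4)))
  rep_ <- evaluate_classification(res)
  ps <- tidy(rep_)
  expect_equal(ps$fraction_correct[ps$sample_id == "a"], 0.75)
  expect_equal(ps$fraction_correct[ps$sample_id == "b"], 0.75)
  expect_equal(rep_$per_class_macro[["tumor"]], 0.75)
  # true-class posterior >= 0.95: tumor rows 1,2 and normal rows 5,6 (and 7: 0.7 < 0.95)
  expect_equal(rep_$posterior_summary[["frac_ge_095"]], 4 / 8)
  g <- glance(rep_)
  expect_equal(g$correct_rate, 0.75)
})

test_that("pooled correct rate equals the class-size-weighted mean of per-class rates", {
  set.seed(77)
  for (i in 1:100) {
    cm <- sample(0:30, 4, replace = TRUE)
    if (cm[1] + cm[4] == 0 || cm[2] + cm[3] == 0) next
    rep_ <- evaluate_classification(fake_results(cm[1], cm[2], cm[3], cm[4]))
    n_pos <- cm[1] + cm[4]; n_neg <- cm[2] + cm[3]
    weighted <- (n_pos * rep_$per_class[["tumor"]] +
                   n_neg * rep_$per_class[["normal"]]) / (n_pos + n_neg)
    expect_equal(rep_$correct_rate, weighted)
  }
})

test_that("patient-level splits keep all of a patient on one side", {
  df <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p4", "p4"),
    tissue_label = c("normal", "tumor", "normal", "tumor", "tumor",
                     "normal", "tumor"))
  sp <- split_by_patient(df, 2, seed = 1)
  expect_length(sp$test_patients, 2)
  expect_length(intersect(sp$test_patients, sp$train_patients), 0)
  # p3 has only a tumor sample: never eligible for the test set
  expect_false("p3" %in% sp$test_patients)
  expect_identical(sp$test_patients,
                   split_by_patient(df, 2, seed = 1)$test_patients)
  expect_error(split_by_patient(df, 4), "insufficient matched")
})

test_that("LOSO runs one fold per sample and nails separable cohorts", {
  set.seed(10)
  df <- gaussian_feature_cohort(12, 3, d = 2, delta = 12)  # far apart
  cv <- loso_cv(df, model_type = "linear")
  expect_equal(cv$n_folds, 6)
  expect_equal(nrow(cv$predictions), nrow(df))
  expect_equal(cv$report$correct_rate, 1)
})

test_that("LOSO errors when a fold's training set lacks a class", {
  set.seed(10)
  df <- gaussian_feature_cohort(6, 1, d = 2, delta = 1)  # one sample/class
  expect_error(loso_cv(df), "lacks a class")
})

test_that("the prior-only classifier reproduces the majority-class rate under LOSO", {
  set.seed(55)
  # unbalanced cohort: every fold keeps tumor as the majority class
  df <- dplyr::bind_rows(
    gaussian_feature_cohort(10, 3, d = 2, delta = 0.5) |>
      dplyr::filter(.data$tissue_label == "normal"),
    gaussian_feature_cohort(10, 8, d = 2, delta = 0.5) |>
      dplyr::filter(.data$tissue_label == "tumor"))
  cv <- loso_cv(df, model_type = "prior")
  expect_equal(cv$report$correct_rate, mean(df$tissue_label == "tumor"))
})

test_that("select_model scores every candidate and breaks ties as documented", {
  set.seed(90)
  cfg <- tiny_config(separability = 1)
  feats <- extract_features(generate_cohort(cfg), feature_spec_full())
  # quadratic candidates on this tiny cohort legitimately warn (n <= dim)
  sel <- suppressWarnings(
    select_model(feats, candidates = default_candidate_specs(),
                 model_types = c("linear", "quadratic")))
  expect_equal(nrow(sel$table), 6)
  expect_setequal(unique(sel$table$spec_name),
                  c("full", "selected", "cars_only"))
  best_rate <- max(sel$table$correct_rate)
  expect_equal(
    sel$table$correct_rate[sel$table$spec_name == sel$best_spec_name &
                             sel$table$model_type == sel$best_model_type],
    best_rate)
  # ties break toward fewer features, then linear
  tied <- sel$table[sel$table$correct_rate == best_rate, ]
  expect_equal(sel$table$n_features[sel$table$spec_name == sel$best_spec_name][1],
               min(tied$n_features))

  single <- select_model(feats,
                         candidates = default_candidate_specs()["selected"],
                         model_types = "linear")
  expect_equal(nrow(single$table), 1)
  expect_identical(single$best_spec_name, "selected")
})
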