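#' Summarize classification results against ground truth
#'
#' Pools all images into one confusion table with tumor as the positive
#' class, and derives the reported rates: correct rate
#' `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` (with tumor positive these equal the pooled per-class
#' correct rates), macro-averaged per-class rates (mean over samples of
#' each sample's fraction correct), a per-sample table, and the fraction
#' of images whose posterior for the true class is at least 0.95 / 0.99.
#'
#' @param results Tibble from [classify_images()]; every row must carry a
#'   `truth` label, and `sample_id` is used for the per-sample table when
#'   present.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_classification <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    stop("no classification results to evaluate", call. = FALSE)
  }
  if (!"truth" %in% names(results) || anyNA(results$truth)) {
    stop("every result must carry a truth label", call. = FALSE)
  }
  pred <- results$predicted
  truth <- results$truth
  tp <- sum(pred == "tumor" & truth == "tumor")
  tn <- sum(pred == "normal" & truth == "normal")
  fp <- sum(pred == "tumor" & truth == "normal")
  fn <- sum(pred == "normal" & truth == "tumor")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_

  per_sample <- NULL
  macro <- c(normal = NA_real_, tumor = NA_real_)
  if ("sample_id" %in% names(results)) {
    per_sample <- results |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        tissue_label = dplyr::first(.data$truth),
        n_images = dplyr::n(),
        fraction_correct = mean(.data$predicted == .data$truth),
        .groups = "drop")
    macro <- vapply(c("normal", "tumor"), function(k) {
      f <- per_sample$fraction_correct[per_sample$tissue_label == k]
      if (length(f)) mean(f) else NA_real_
    }, numeric(1))
  }
  post_true <- if ("posterior_tumor" %in% names(results)) {
    ifelse(truth == "tumor", results$posterior_tumor,
           1 - results$posterior_tumor)
  } else NULL
  structure(
    list(confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
         n = length(pred),
         correct_rate = (tp + tn) / length(pred),
         sensitivity = sens,
         specificity = spec,
         per_class = c(normal = spec, tumor = sens),
         per_class_macro = macro,
         per_sample = per_sample,
         posterior_summary = if (!is.null(post_true)) {
           c(frac_ge_095 = mean(post_true >= 0.95 & pred == truth),
             frac_ge_099 = mean(post_true >= 0.99 & pred == truth))
         }),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: n = %d images>\n", x$n))
  cat(sprintf("  correct rate %.1f%% | sensitivity %.1f%% | specificity %.1f%%\n",
              100 * x$correct_rate, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  macro per-class: normal %.1f%%, tumor %.1f%%\n",
              100 * x$per_class_macro[["normal"]],
              100 * x$per_class_macro[["tumor"]]))
  if (!is.null(x$posterior_summary)) {
    cat(sprintf("  correctly classified with true-class posterior >= 0.95: %.1f%%\n",
                100 * x$posterior_summary[["frac_ge_095"]]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.evaluation_report <- function(x, ...) {
  x$per_sample %||%
    tibble::tibble(sample_id = character(), tissue_label = character(),
                   n_images = integer(), fraction_correct = numeric())
}

#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, tp = x$confusion[["tp"]], tn = x$confusion[["tn"]],
    fp = x$confusion[["fp"]], fn = x$confusion[["fn"]],
    correct_rate = x$correct_rate, sensitivity = x$sensitivity,
    specificity = x$specificity,
    correct_rate_normal_macro = x$per_class_macro[["normal"]],
    correct_rate_tumor_macro = x$per_class_macro[["tumor"]],
    frac_posterior_ge_095 = if (is.null(x$posterior_summary)) NA_real_
                            else x$posterior_summary[["frac_ge_095"]],
    frac_posterior_ge_099 = if (is.null(x$posterior_summary)) NA_real_
                            else x$posterior_summary[["frac_ge_099"]])
}

#' Per-sample fraction of correctly classified images
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot bar chart, one bar per sample, split by tissue label.
#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_report <- function(object, ...) {
  stopifnot(!is.null(object$per_sample))
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$fraction_correct,
                               fill = .data$tissue_label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(normal = "#78b4e6",
                                          tumor = "#e67814")) +
    ggplot2::labs(x = "sample", y = "fraction of images correctly classified",
                  fill = "tissue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Split a cohort into training and test patients
#'
#' Every image of a patient lands on exactly one side. Only patients with
#' both matched tissue types are eligible for the test set; patients with
#' a single sample always stay in training.
#'
#' @param features Feature tibble (or any tibble with `patient_id` and
#'   `tissue_label` columns).
#' @param n_test_matched Number of matched patients to assign to the test
#'   set.
#' @param seed Optional integer; when given, the draw is made under this
#'   seed and is reproducible.
#' @return A list of class `split_plan` with `test_patients` and
#'   `train_patients` (disjoint character vectors).
#' @export
split_by_patient <- function(features, n_test_matched, seed = NULL) {
  stopifnot(all(c("patient_id", "tissue_label") %in% names(features)))
  by_pat <- features |>
    dplyr::distinct(.data$patient_id, .data$tissue_label) |>
    dplyr::count(.data$patient_id)
  matched <- by_pat$patient_id[by_pat$n == 2]
  if (length(matched) < n_test_matched) {
    stop("insufficient matched patients: have ", length(matched),
         ", need ", n_test_matched, call. = FALSE)
  }
  draw <- function() sort(sample(matched, n_test_matched))
  test <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(test_patients = test,
         train_patients = sort(setdiff(unique(features$patient_id), test))),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d test / %d training patients>\n",
              length(x$test_patients), length(x$train_patients)))
  invisible(x)
}

#' Leave-one-sample-out cross-validation
#'
#' For each tissue sample, all its images are classified by a model
#' trained on the images of every other sample; the held-out predictions
#' are pooled into one evaluation report. The number of folds equals the
#' number of samples.
#'
#' @param features Feature tibble with `sample_id` and `tissue_label`
#'   columns plus the feature columns.
#' @param spec Optional [feature_spec()] selecting/ordering the feature
#'   columns.
#' @param model_type `"linear"`, `"quadratic"`, or `"prior"`.
#' @param priors `"empirical"` or `"uniform"`.
#' @return An object of class `loso_result`: `report` (an
#'   `evaluation_report`), `predictions` (tibble of held-out
#'   classifications), `n_folds`.
#' @export
loso_cv <- function(features, spec = NULL,
                    model_type = c("linear", "quadratic", "prior"),
                    priors = c("empirical", "uniform")) {
  model_type <- match.arg(model_type)
  priors <- match.arg(priors)
  stopifnot(all(c("sample_id", "tissue_label") %in% names(features)))
  samples <- unique(features$sample_id)
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  preds <- purrr::map_dfr(samples, function(s) {
    train <- features[features$sample_id != s, , drop = FALSE]
    if (length(unique(train$tissue_label)) < 2) {
      stop("training set for held-out sample '", s, "' lacks a class",
           call. = FALSE)
    }
    model <- fit_discriminant(train, spec = spec, model_type = model_type,
                              priors = priors)
    classify_images(model, features[features$sample_id == s, , drop = FALSE])
  })
  structure(
    list(report = evaluate_classification(preds), predictions = preds,
         n_folds = length(samples)),
    class = "loso_result"
  )
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result: %d folds>\n", x$n_folds))
  print(x$report)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.loso_result <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.loso_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_folds = x$n_folds), glance(x$report))
}

#' Default candidate feature subsets for model selection
#'
#' Channel-structured subsets: all channels full, the selected
#' configuration (full CARS and TPEF, SHG first-order plus contrast), and
#' CARS only.
#'
#' @inheritParams feature_spec
#' @return Named list of [feature_spec()] objects.
#' @export
default_candidate_specs <- function(distances = c(1L, 12L, 30L),
                                    levels = 8L, symmetric = FALSE) {
  list(full = feature_spec_full(distances, levels, symmetric),
       selected = feature_spec_selected(distances, levels, symmetric),
       cars_only = feature_spec_cars_only(distances, levels, symmetric))
}

#' Select a classifier configuration by cross-validated correct rate
#'
#' Evaluates every (feature subset, model type) candidate by
#' leave-one-sample-out correct rate and returns the argmax; ties are
#' broken toward fewer features, then toward the linear model.
#'
#' @param features Feature tibble covering the union of candidate
#'   columns (extract with [feature_spec_full()]).
#' @param candidates Named list of [feature_spec()] objects.
#' @param model_types Character subset of `c("linear", "quadratic")`.
#' @param priors `"empirical"` or `"uniform"`.
#' @return List of class `model_selection`: `best_spec`,
#'   `best_spec_name`, `best_model_type`, and `table` (one row per
#'   candidate with its score) for audit.
#' @export
select_model <- function(features, candidates = default_candidate_specs(),
                         model_types = c("linear", "quadratic"),
                         priors = c("empirical", "uniform")) {
  stopifnot(length(candidates) >= 1, !is.null(names(candidates)))
  priors <- match.arg(priors)
  model_types <- match.arg(model_types, several.ok = TRUE)
  grid <- tidyr::expand_grid(spec_name = names(candidates),
                             model_type = model_types)
  tab <- purrr::pmap_dfr(grid, function(spec_name, model_type) {
    spec <- candidates[[spec_name]]
    cv <- loso_cv(features, spec = spec, model_type = model_type,
                  priors = priors)
    tibble::tibble(spec_name = spec_name, model_type = model_type,
                   n_features = length(feature_names(spec)),
                   correct_rate = cv$report$correct_rate)
  })
  ranked <- tab |>
    dplyr::arrange(dplyr::desc(.data$correct_rate), .data$n_features,
                   match(.data$model_type, c("linear", "quadratic")))
  best <- ranked[1, ]
  structure(
    list(best_spec = candidates[[best$spec_name]],
         best_spec_name = best$spec_name,
         best_model_type = best$model_type,
         table = tab),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection: best = %s / %s>\n", x$best_spec_name,
              x$best_model_type))
  print(x$table)
  invisible(x)
}
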