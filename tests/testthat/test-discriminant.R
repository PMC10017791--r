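two_class_1d <- function() {
  tibble::tibble(
    sample_id = rep(c("a", "b"), each = 4),
    tissue_label = rep(c("normal", "tumor"), each = 4),
    f1 = c(0, 0, 2, 2, 4, 4, 6, 6))
}

test_that("fit matches hand arithmetic: means and pooled variance with divisor N-K", {
  m <- fit_discriminant(two_class_1d(), model_type = "linear")
  expect_equal(unname(m$means[, "f1"]), c(1, 5))
  expect_equal(m$cov$pooled[1, 1], 4 / 3)   # (4 + 4) / (8 - 2)
  expect_equal(unname(m$priors), c(0.5, 0.5))
})

test_that("class means are invariant to replicating every training point", {
  df <- two_class_1d()
  m1 <- fit_discriminant(df, model_type = "linear")
  m2 <- fit_discriminant(dplyr::bind_rows(df, df), model_type = "linear")
  expect_equal(m1$means, m2$means)
  expect_equal(m1$priors, m2$priors)
})

test_that("quadratic fit collapses to the linear fit when per-class covariances are equal", {
  set.seed(8)
  X <- matrix(rnorm(60 * 3), 60, 3)
  # second class is a pure shift of the first: identical sample covariance
  df <- tibble::tibble(tissue_label = rep(c("normal", "tumor"), each = 60))
  feats <- rbind(X, X + matrix(c(2, -1, 0.5), 60, 3, byrow = TRUE))
  colnames(feats) <- paste0("f", 1:3)
  df <- dplyr::bind_cols(df, tibble::as_tibble(feats))
  lda <- fit_discriminant(df, model_type = "linear")
  qda <- fit_discriminant(df, model_type = "quadratic")
  new <- tibble::as_tibble(matrix(rnorm(40 * 3, sd = 2), 40, 3,
                                  dimnames = list(NULL, paste0("f", 1:3))))
  expect_equal(posterior(lda, new)$posterior_tumor,
               posterior(qda, new)$posterior_tumor, tolerance = 1e-9)
})

test_that("posteriors agree with brute-force Gaussian density evaluation", {
  set.seed(17)
  n <- 40; d <- 4
  df <- tibble::tibble(tissue_label = rep(c("normal", "tumor"), each = n))
  feats <- rbind(matrix(rnorm(n * d), n, d),
                 matrix(rnorm(n * d, mean = 1.2), n, d))
  colnames(feats) <- paste0("f", seq_len(d))
  df <- dplyr::bind_cols(df, tibble::as_tibble(feats))
  for (type in c("linear", "quadratic")) {
    m <- fit_discriminant(df, model_type = type)
    Xnew <- matrix(rnorm(100 * d, sd = 1.5), 100, d,
                   dimnames = list(NULL, paste0("f", seq_len(d))))
    covs <- if (type == "linear") list(m$cov$pooled, m$cov$pooled)
            else list(m$cov$normal, m$cov$tumor)
    oracle <- posterior_oracle(Xnew, m$means, covs, m$priors)
    got <- posterior(m, tibble::as_tibble(Xnew))
    expect_lt(max(abs(got$posterior_tumor - oracle[, 2])), 1e-10)
    expect_equal(got$posterior_normal + got$posterior_tumor,
                 rep(1, 100), tolerance = 1e-12)
  }
})

test_that("a point equidistant from both means gets posterior one half", {
  df <- tibble::tibble(
    tissue_label = rep(c("normal", "tumor"), each = 3),
    f1 = c(-1, 0, 1, 3, 4, 5))
  m <- fit_discriminant(df, model_type = "linear")
  p <- posterior(m, tibble::tibble(f1 = 2))     # midpoint of 0 and 4
  expect_equal(p$posterior_tumor, 0.5)
  # and at a class mean of well-separated classes the posterior saturates
  df2 <- tibble::tibble(
    tissue_label = rep(c("normal", "tumor"), each = 50),
    f1 = c(rnorm(50, 0, 0.3), rnorm(50, 10, 0.3)))
  m2 <- fit_discriminant(df2, model_type = "linear")
  expect_gt(posterior(m2, tibble::tibble(f1 = m2$means["tumor", ]))$posterior_tumor,
            0.99)
})

test_that("the linear decision boundary is affine (midpoints stay on it)", {
  set.seed(30)
  d <- 3
  df <- tibble::tibble(tissue_label = rep(c("normal", "tumor"), each = 50))
  feats <- rbind(matrix(rnorm(50 * d), 50, d),
                 matrix(rnorm(50 * d, mean = 1), 50, d))
  colnames(feats) <- paste0("f", 1:d)
  m <- fit_discriminant(dplyr::bind_cols(df, tibble::as_tibble(feats)),
                        model_type = "linear")
  # find boundary points along random segments by bisection on the logit
  diff_post <- function(x) {
    posterior(m, tibble::as_tibble(matrix(x, 1, dimnames = list(NULL,
      paste0("f", 1:d)))))$posterior_tumor - 0.5
  }
  boundary_point <- function() {
    a <- m$means["normal", ]; b <- m$means["tumor", ] + rnorm(d, sd = 0.3)
    f <- function(t) diff_post(a + t * (b - a))
    t0 <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
    a + t0 * (b - a)
  }
  p1 <- boundary_point(); p2 <- boundary_point()
  expect_lt(abs(diff_post((p1 + p2) / 2)), 1e-8)
})

test_that("classification applies the 0.5 rule with the conservative tie convention", {
  df <- two_class_1d()
  m <- fit_discriminant(df, model_type = "linear")
  res <- classify_images(m, dplyr::mutate(df, fov_id = as.character(1:8)))
  expect_equal(nrow(res), 8)
  expect_identical(res$fov_id, as.character(1:8))   # order preserved
  expect_identical(res$predicted,
                   ifelse(res$posterior_tumor > 0.5, "tumor", "normal"))
  # the midpoint scores exactly 0.5 and is assigned to normal
  mid <- classify_images(m, tibble::tibble(f1 = 3))
  expect_equal(mid$posterior_tumor, 0.5)
  expect_identical(mid$predicted, "normal")
})

test_that("error contracts: small classes, non-finite rows, dimension mismatch", {
  expect_error(fit_discriminant(tibble::tibble(
    tissue_label = c("normal", "tumor", "tumor"), f1 = 1:3)),
    "fewer than 2")
  df <- two_class_1d()
  df$f1[3] <- NA
  expect_error(fit_discriminant(df), "non-finite feature value in row 3")
  m <- fit_discriminant(two_class_1d())
  expect_error(posterior(m, tibble::tibble(g = 1)), "absent")
})

test_that("posteriors agree with an independent reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(41)
  df <- gaussian_feature_cohort(20, 3, d = 5, delta = 1.5)
  m <- fit_discriminant(df, model_type = "linear")
  fit <- MASS::lda(as.matrix(df[, paste0("f", 1:5)]),
                   grouping = factor(df$tissue_label,
                                     levels = c("normal", "tumor")))
  new <- matrix(rnorm(50 * 5), 50, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
  ref <- stats::predict(fit, new)$posterior[, "tumor"]
  got <- posterior(m, tibble::as_tibble(new))$posterior_tumor
  expect_equal(got, unname(ref), tolerance = 1e-6)
})

test_that("accuracy approaches the analytic Bayes rate for shared-covariance Gaussians", {
  set.seed(2024)
  d <- 4
  delta <- 1.68                      # Mahalanobis distance between means
  sigma <- 0.6 * diag(d) + 0.4      # equicorrelated
  R <- chol(sigma)
  mu <- rep(delta, d) / sqrt(drop(t(rep(1, d)) %*% solve(sigma) %*% rep(1, d)))
  draw <- function(n, shift) {
    X <- matrix(rnorm(n * d), n, d) %*% R
    if (shift) X <- X + matrix(mu, n, d, byrow = TRUE)
    X
  }
  train <- rbind(draw(2000, FALSE), draw(2000, TRUE))
  colnames(train) <- paste0("f", 1:d)
  df <- dplyr::bind_cols(
    tibble::tibble(tissue_label = rep(c("normal", "tumor"), each = 2000)),
    tibble::as_tibble(train))
  m <- fit_discriminant(df, model_type = "linear")
  test <- rbind(draw(10000, FALSE), draw(10000, TRUE))
  colnames(test) <- paste0("f", 1:d)
  truth <- rep(c("normal", "tumor"), each = 10000)
  pred <- classify_images(m, tibble::as_tibble(test))$predicted
  acc <- mean(pred == truth)
  bayes <- pnorm(delta / 2)
  expect_lt(abs(acc - bayes), 0.02)
})

test_that("model JSON round-trips and reproduces posteriors", {
  set.seed(12)
  df <- gaussian_feature_cohort(15, 2, d = 3, delta = 1)
  for (type in c("linear", "quadratic")) {
    m <- fit_discriminant(df, model_type = type)
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path)
    m2 <- read_model(path)
    new <- tibble::as_tibble(matrix(rnorm(30), 10, 3,
                                    dimnames = list(NULL, paste0("f", 1:3))))
    expect_equal(posterior(m, new)$posterior_tumor,
                 posterior(m2, new)$posterior_tumor, tolerance = 1e-10)
  }
})

test_that("tidy and glance summarize a fitted model", {
  df <- gaussian_feature_cohort(10, 2, d = 3, delta = 1)
  m <- fit_discriminant(df, model_type = "linear")
  td <- tidy(m)
  expect_equal(nrow(td), 6)          # 2 classes x 3 features
  g <- glance(m)
  expect_equal(g$n_features, 3)
  expect_equal(g$n_normal, 20)
})
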