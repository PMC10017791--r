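test_that("min-max normalization has the stated closed form and degenerate convention", {
  r <- matrix(c(2, 6, 10, 4), 2, 2)
  n <- normalize_channel(r)
  expect_equal(n[1, 2], 1)          # max -> 1
  expect_equal(n[2, 1], (6 - 2) / 8)
  expect_equal(n[2, 2], (4 - 2) / 8)
  expect_equal(n[1, 1], 0)          # min -> 0
  expect_false(attr(n, "degenerate"))

  expect_warning(nc <- normalize_channel(matrix(5, 3, 3)), "degenerate")
  expect_true(all(nc == 0))
  expect_true(attr(nc, "degenerate"))

  already <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  expect_equal(unclass(normalize_channel(already)),
               unclass(already), ignore_attr = TRUE)
})

test_that("first-order statistics match closed forms", {
  # constant raster: all degenerate conventions kick in
  fo <- first_order_features(matrix(0.3, 5, 5))
  expect_equal(unname(fo[c("sd", "kurtosis", "skewness", "entropy")]),
               c(0, 0, 0, 0))

  # half zeros, half ones: two-point symmetric distribution
  fo <- first_order_features(matrix(c(rep(0, 8), rep(1, 8)), 4, 4))
  expect_equal(fo[["mean"]], 0.5)
  expect_equal(fo[["sd"]], 0.5)
  expect_equal(fo[["entropy"]], 1)
  expect_equal(fo[["skewness"]], 0)
  expect_equal(fo[["kurtosis"]], 1)

  # large Gaussian sample: non-excess kurtosis approaches 3
  set.seed(11)
  x <- matrix(0.5 + 0.07 * rnorm(400 * 400), 400, 400)
  stopifnot(min(x) > 0, max(x) < 1)   # no clipping distorts moments
  fo <- first_order_features(x)
  expect_equal(fo[["kurtosis"]], 3, tolerance = 0.05)
  expect_equal(fo[["skewness"]], 0, tolerance = 0.05)
})

test_that("GLCM matches hand enumeration on the 2x2 example", {
  r <- matrix(c(0, 1, 0, 1), 2, 2)  # rows: (0,0) / (1,1)
  P0 <- glcm(r, 1, 0, levels = 2)
  expect_equal(P0, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  P90 <- glcm(r, 1, 90, levels = 2)
  expect_equal(P90, matrix(c(0, 1, 0, 0), 2, 2))    # only (1,0) pair
  P90s <- glcm(r, 1, 90, levels = 2, symmetric = TRUE)
  expect_equal(P90s, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("every GLCM is a probability matrix and errors without valid pairs", {
  set.seed(3)
  r <- matrix(runif(63), 7, 9)
  for (o in c(0, 45, 90, 135)) {
    expect_equal(sum(glcm(r, 2, o, levels = 5)), 1)
  }
  expect_error(glcm(r, 20, 0, levels = 4), "no valid pairs")
})

test_that("GLCM equals the brute-force pair-enumeration oracle", {
  set.seed(99)
  for (i in 1:25) {
    nr <- sample(2:16, 1); nc <- sample(2:16, 1)
    r <- matrix(runif(nr * nc), nr, nc)
    lv <- sample(2:4, 1)
    d <- sample(1:3, 1)
    if (d >= nr || d >= nc) d <- 1
    for (o in c(0, 45, 90, 135)) {
      for (sym in c(FALSE, TRUE)) {
        expect_equal(glcm(r, d, o, lv, sym), glcm_oracle(r, d, o, lv, sym),
                     info = sprintf("n=%dx%d d=%d o=%d sym=%d", nr, nc, d,
                                    o, sym))
      }
    }
  }
})

test_that("GLCM statistics match closed forms and bounds", {
  # diagonal matrix: perfectly homogeneous
  P <- diag(c(0.4, 0.6))
  g <- glcm_features(P)
  expect_equal(g[["contrast"]], 0)
  expect_equal(g[["homogeneity"]], 1)

  # uniform 2x2
  g <- glcm_features(matrix(0.25, 2, 2))
  expect_equal(g[["energy"]], 0.25)
  expect_equal(g[["contrast"]], 0.5)
  expect_equal(g[["homogeneity"]], 0.75)
  expect_equal(g[["correlation"]], 0)

  # all mass in one cell: degenerate correlation convention
  P1 <- matrix(0, 3, 3); P1[1, 1] <- 1
  g <- glcm_features(P1)
  expect_equal(g[["energy"]], 1)
  expect_equal(g[["correlation"]], 0)

  expect_error(glcm_features(matrix(0.4, 2, 2)), "not normalized")

  set.seed(5)
  for (i in 1:20) {
    P <- matrix(rexp(16), 4, 4); P <- P / sum(P)
    g <- glcm_features(P)
    expect_gte(g[["contrast"]], 0)
    expect_true(g[["energy"]] > 0 && g[["energy"]] <= 1)
    expect_true(g[["homogeneity"]] > 0 && g[["homogeneity"]] <= 1)
    expect_lte(abs(g[["correlation"]]), 1 + 1e-12)
  }
})

test_that("specs produce the documented feature counts and fixed order", {
  expect_length(feature_names(feature_spec_full()), 51)
  sel <- feature_spec_selected()
  nm <- feature_names(sel)
  expect_length(nm, 42)
  expect_length(grep("^cars_", nm), 17)
  expect_length(grep("^tpef_", nm), 17)
  expect_length(grep("^shg_", nm), 8)
  # SHG keeps only first-order + contrast
  expect_identical(grep("^shg_", nm, value = TRUE),
                   c("shg_mean", "shg_sd", "shg_kurtosis", "shg_skewness",
                     "shg_entropy", "shg_contrast_d1", "shg_contrast_d12",
                     "shg_contrast_d30"))
  # fixed within-channel order: first-order then per-distance blocks
  expect_identical(nm[1:9],
                   c("cars_mean", "cars_sd", "cars_kurtosis",
                     "cars_skewness", "cars_entropy", "cars_contrast_d1",
                     "cars_correlation_d1", "cars_energy_d1",
                     "cars_homogeneity_d1"))
  expect_length(feature_names(feature_spec_cars_only()), 17)
  expect_error(feature_spec(list(dapi = full_channel())), "unknown channel")
})

test_that("extraction is invariant to channel gain and to 90-degree rotation (symmetric GLCM, square raster)", {
  set.seed(21)
  m <- matrix(runif(40 * 40), 40, 40)
  f1 <- fov_image(m * 1000, m * 3, m * 7)
  f2 <- fov_image(m * 35, m * 800, m * 0.5 + 0)   # different gains only
  spec <- feature_spec_full(distances = c(1L, 3L), levels = 6)
  expect_equal(extract_features(f1, spec), extract_features(f2, spec),
               tolerance = 1e-12)

  rot <- t(m)[, nrow(m):1]                        # 90-degree rotation
  spec_sym <- feature_spec(list(cars = full_channel()),
                           distances = c(1L, 4L), levels = 6,
                           symmetric = TRUE)
  a <- extract_features(fov_image(m, m, m), spec_sym)
  b <- extract_features(fov_image(rot, rot, rot), spec_sym)
  second_order <- grep("_d[0-9]+$", names(a), value = TRUE)
  expect_equal(as.numeric(a[second_order]), as.numeric(b[second_order]),
               tolerance = 1e-10)
})

test_that("extraction over a sample carries provenance and spec order", {
  cfg <- tiny_config()
  coh <- generate_cohort(cfg)
  ft <- extract_features(coh[[1]], feature_spec_selected())
  expect_equal(nrow(ft), cfg$tiles_per_sample)
  expect_identical(names(ft)[1:6],
                   c("patient_id", "sample_id", "tissue_label", "fov_id",
                     "tile_row", "tile_col"))
  expect_identical(names(ft)[-(1:6)],
                   feature_names(feature_spec_selected()))
  expect_true(all(is.finite(as.matrix(ft[, -(1:6)]))))
})
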