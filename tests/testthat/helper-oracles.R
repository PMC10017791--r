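# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive enumeration / direct density formulas and
# share no code with the package internals.

# pair-enumeration GLCM: loop over every pixel, follow the offset, count
glcm_oracle <- function(raster, distance, orientation, levels,
                        symmetric = FALSE) {
  d <- as.integer(distance)
  off <- switch(as.character(orientation),
                "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
                "135" = c(-d, -d))
  q <- pmin(floor(raster * levels) + 1L, levels)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(raster))) {
    for (cc in seq_len(ncol(raster))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(raster) && c2 >= 1 && c2 <= ncol(raster)) {
        counts[q[r, cc], q[r2, c2]] <- counts[q[r, cc], q[r2, c2]] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# direct two-class Gaussian posterior via solve()/det(), no log tricks
posterior_oracle <- function(X, means, covs, priors) {
  dens <- function(x, mu, S) {
    d <- length(mu)
    v <- x - mu
    exp(-0.5 * drop(t(v) %*% solve(S) %*% v)) /
      sqrt((2 * pi)^d * det(S))
  }
  t(apply(X, 1, function(x) {
    w <- c(priors[1] * dens(x, means[1, ], covs[[1]]),
           priors[2] * dens(x, means[2, ], covs[[2]]))
    w / sum(w)
  }))
}

# feature tibble drawn from two known Gaussians (no images involved)
gaussian_feature_cohort <- function(n_per_sample, n_samples_per_class, d,
                                    delta, sigma = diag(d)) {
  R <- chol(sigma)
  rows <- list()
  for (cls in c("normal", "tumor")) {
    mu <- if (cls == "tumor") rep(delta / sqrt(d), d) else rep(0, d)
    for (s in seq_len(n_samples_per_class)) {
      X <- matrix(rnorm(n_per_sample * d), n_per_sample, d) %*% R +
        matrix(mu, n_per_sample, d, byrow = TRUE)
      colnames(X) <- paste0("f", seq_len(d))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(
          patient_id = sprintf("%s%02d", toupper(substr(cls, 1, 1)), s),
          sample_id = sprintf("%s_%02d", cls, s),
          tissue_label = cls,
          fov_id = sprintf("%s_%02d_%03d", cls, s, seq_len(n_per_sample)),
          tile_row = 0L, tile_col = seq_len(n_per_sample) - 1L),
        tibble::as_tibble(X))
    }
  }
  dplyr::bind_rows(rows)
}

# small, fast synthetic config for image-level tests
tiny_config <- function(...) {
  synthetic_config(fov_shape = c(48L, 48L), n_patients_matched = 2L,
                   tiles_per_sample = 3L, seed = 42L, ...)
}

flat_fov <- function(value, nr = 8, nc = 8, tile_row = 0L, tile_col = 0L,
                     fov_id = "flat") {
  m <- matrix(value, nr, nc)
  fov_image(m, m, m, tile_row = tile_row, tile_col = tile_col,
            fov_id = fov_id)
}
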