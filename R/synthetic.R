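.mpmtex_cache <- new.env(parent = emptyenv())

gauss_kernel_matrix <- function(n, sigma) {
  key <- sprintf("K_%d_%g", n, sigma)
  if (!is.null(.mpmtex_cache[[key]])) return(.mpmtex_cache[[key]])
  idx <- seq_len(n)
  K <- exp(-0.5 * (outer(idx, idx, "-") / sigma)^2)
  K <- K / rowSums(K)
  .mpmtex_cache[[key]] <- K
  K
}

# separable Gaussian smoothing by banded matrix products (cached kernels)
smooth_field <- function(X, sigma) {
  Kr <- gauss_kernel_matrix(nrow(X), sigma)
  Kc <- gauss_kernel_matrix(ncol(X), sigma)
  Kr %*% X %*% t(Kc)
}

smooth_noise <- function(nr, nc, sigma) {
  S <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  s <- stats::sd(S)
  if (s == 0) return(S)
  S / s
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Configure the synthetic two-class cohort generator
#'
#' Defines a seeded generative model for three-channel FoV tiles whose
#' texture statistics differ by tissue class. Tumor tiles mix gland/nest
#' ring motifs into CARS and TPEF and carry dense SHG stroma fibers;
#' normal tiles show quasi-periodic hepatocyte-cord banding with sparse
#' SHG and lipid droplets in CARS. The class difference is injected
#' through motif weights and densities (texture), not through mean
#' brightness, so second-order (GLCM) features carry class signal.
#'
#' `separability` scales the parameter gap between the two classes: at 0
#' both classes are drawn from the identical generative distribution; at
#' 1 each class sits at its own motif target. Identical seed and config
#' give a bit-identical cohort; each FoV consumes an RNG substream keyed
#' by (patient, sample, tile).
#'
#' @param fov_shape Integer `(rows, cols)` per tile, default `c(152, 302)`
#'   (1 um/pixel).
#' @param n_patients_matched Patients contributing both a tumor and a
#'   normal sample. Default 8.
#' @param n_tumor_only,n_normal_only Patients with a single sample.
#'   Default 0.
#' @param tiles_per_sample Tiles per sample, default 30.
#' @param separability Real in `[0, 1]`, default 1.
#' @param noise_model `"poisson"` (shot noise; `noise_scale` is the
#'   expected count at unit clean intensity, default 20000) or
#'   `"gaussian"` (additive; `noise_scale` is the sd in counts, default
#'   1000).
#' @param noise_scale Noise scale; `NULL` picks the per-model default.
#' @param motifs Named list of motif parameters (pixels/counts per tile):
#'   `gland_radius` (18), `gland_density` (6), `stroma_fiber_density`
#'   (tumor target fiber count, 14), `cord_period` (24),
#'   `droplet_radius` (3), `droplet_density` (normal target droplet
#'   count, 25).
#' @param intensity_scale Counts at unit clean intensity (16-bit head
#'   room), default 20000.
#' @param seed Base RNG seed, default 1.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(fov_shape = c(152L, 302L),
                             n_patients_matched = 8L,
                             n_tumor_only = 0L, n_normal_only = 0L,
                             tiles_per_sample = 30L,
                             separability = 1,
                             noise_model = c("poisson", "gaussian"),
                             noise_scale = NULL,
                             motifs = list(),
                             intensity_scale = 20000,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(separability >= 0, separability <= 1,
            tiles_per_sample >= 1, n_patients_matched >= 0)
  if (is.null(noise_scale)) {
    noise_scale <- if (noise_model == "poisson") 20000 else 1000
  }
  m <- utils::modifyList(
    list(gland_radius = 18, gland_density = 6, stroma_fiber_density = 14,
         cord_period = 24, droplet_radius = 3, droplet_density = 25),
    motifs)
  structure(
    list(fov_shape = as.integer(fov_shape),
         n_patients_matched = as.integer(n_patients_matched),
         n_tumor_only = as.integer(n_tumor_only),
         n_normal_only = as.integer(n_normal_only),
         tiles_per_sample = as.integer(tiles_per_sample),
         separability = separability,
         noise_model = noise_model, noise_scale = noise_scale,
         motifs = m, intensity_scale = intensity_scale,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config %dx%d px, %d matched (+%d/+%d single) patients x %d tiles, separability %.2f, %s noise, seed %d>\n",
    x$fov_shape[1], x$fov_shape[2], x$n_patients_matched, x$n_tumor_only,
    x$n_normal_only, x$tiles_per_sample, x$separability, x$noise_model,
    x$seed))
  invisible(x)
}

# deterministic 31-bit substream seed from the base seed and tile keys
substream_seed <- function(seed, patient, sample, tile) {
  h <- (as.double(seed) %% 2147483647) * 48271
  for (k in c(patient, sample, tile)) {
    h <- (h + as.double(k) * 69621 + 1) %% 2147483647
    h <- (h * 16807) %% 2147483647
  }
  as.integer(h %% 2147483629) + 1L
}

gland_field <- function(nr, nc, n_glands, radius) {
  G <- matrix(0, nr, nc)
  if (n_glands < 1) return(G)
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(n_glands)) {
    cy <- stats::runif(1, 1, nr); cx <- stats::runif(1, 1, nc)
    r <- radius * stats::runif(1, 0.7, 1.3)
    d <- sqrt((rowg - cy)^2 + (colg - cx)^2)
    # bright epithelial ring around a dark lumen
    G <- G + exp(-((d - r) / (0.3 * r))^2) - 0.8 * exp(-(d / (0.55 * r))^2)
  }
  pmin(pmax(G, -1), 1)
}

cord_field <- function(nr, nc, period) {
  th <- stats::runif(1, 0, pi)
  ph <- stats::runif(1, 0, 2 * pi)
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  per <- period * stats::runif(1, 0.85, 1.15)
  sin(2 * pi * (rowg * cos(th) + colg * sin(th)) / per + ph)
}

stamp_discs <- function(F, n, radius, amp) {
  nr <- nrow(F); nc <- ncol(F)
  if (n < 1) return(F)
  for (i in seq_len(n)) {
    cy <- stats::runif(1, 1, nr); cx <- stats::runif(1, 1, nc)
    r <- radius * stats::runif(1, 0.7, 1.4)
    w <- ceiling(2.5 * r)
    rows <- max(1, floor(cy - w)):min(nr, ceiling(cy + w))
    cols <- max(1, floor(cx - w)):min(nc, ceiling(cx + w))
    d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
    F[rows, cols] <- F[rows, cols] + amp * exp(-d2 / (0.7 * r)^2)
  }
  F
}

fiber_field <- function(nr, nc, n_fibers) {
  if (n_fibers < 1) return(matrix(0, nr, nc))
  idx <- vector("list", n_fibers)
  for (i in seq_len(n_fibers)) {
    y0 <- stats::runif(1, 1, nr); x0 <- stats::runif(1, 1, nc)
    th <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.3, 0.9) * max(nr, nc)
    curv <- stats::rnorm(1, 0, 0.0015)
    t <- seq(-len / 2, len / 2, by = 0.5)
    ys <- y0 + t * sin(th) + curv * t^2 * cos(th)
    xs <- x0 + t * cos(th) - curv * t^2 * sin(th)
    ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
    idx[[i]] <- round(ys[ok]) + (round(xs[ok]) - 1) * nr
  }
  counts <- tabulate(unlist(idx), nbins = nr * nc)
  smooth_field(matrix(counts, nr, nc), 1.0)
}

clean_fov_fields <- function(tissue_class, config) {
  nr <- config$fov_shape[1]; nc <- config$fov_shape[2]
  s <- config$separability
  delta <- if (tissue_class == "tumor") 1 else -1
  m <- config$motifs

  # class targets sit symmetrically around a common baseline so that
  # separability 0 gives one identical generative distribution
  w_gland <- 0.5 + 0.5 * s * delta
  fiber_target_t <- m$stroma_fiber_density; fiber_target_n <- 1
  fiber_base <- (fiber_target_t + fiber_target_n) / 2
  n_fibers <- round(fiber_base + s * delta * (fiber_target_t - fiber_base))
  drop_target_n <- m$droplet_density; drop_target_t <- 2
  drop_base <- (drop_target_n + drop_target_t) / 2
  n_drops <- round(drop_base - s * delta * (drop_target_n - drop_base))

  G <- gland_field(nr, nc, m$gland_density, m$gland_radius)
  C <- cord_field(nr, nc, m$cord_period)
  cell <- 0.5 + 0.45 * (w_gland * G + (1 - w_gland) * C)
  fine <- smooth_noise(nr, nc, 1.5)
  coarse <- smooth_noise(nr, nc, 8)

  cars <- clip01(0.15 + 0.7 * cell * (1 + 0.18 * fine) + 0.06 * coarse)
  cars <- clip01(stamp_discs(cars, n_drops, m$droplet_radius, 0.55))
  tpef <- clip01(0.18 + 0.65 * cell * (1 + 0.18 * smooth_noise(nr, nc, 1.5)) +
                   0.06 * coarse)
  fib <- fiber_field(nr, nc, n_fibers)
  shg <- clip01(0.01 + 2.2 * fib + 0.01 * abs(smooth_noise(nr, nc, 2)))
  list(cars = cars, tpef = tpef, shg = shg)
}

apply_noise <- function(clean, config) {
  n <- length(clean)
  if (config$noise_model == "poisson") {
    x <- stats::rpois(n, lambda = as.vector(clean) * config$noise_scale)
    x <- x * (config$intensity_scale / config$noise_scale)
  } else {
    x <- as.vector(clean) * config$intensity_scale +
      stats::rnorm(n, sd = config$noise_scale)
  }
  matrix(pmin(pmax(x, 0), 65535), nrow(clean), ncol(clean))
}

#' Generate one synthetic FoV tile
#'
#' Deterministic given `(tissue_class, config, rng_seed)`.
#'
#' @param tissue_class `"normal"` or `"tumor"`.
#' @param config A [synthetic_config()].
#' @param rng_seed Integer substream seed; defaults to the config seed.
#' @param tile_row,tile_col,fov_id Provenance for the returned tile.
#' @return A [fov_image()].
#' @export
generate_fov <- function(tissue_class, config = synthetic_config(),
                         rng_seed = config$seed, tile_row = 0L,
                         tile_col = 0L, fov_id = "synthetic") {
  tissue_class <- match.arg(tissue_class, c("normal", "tumor"))
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(rng_seed, {
    fields <- clean_fov_fields(tissue_class, config)
    fov_image(cars = apply_noise(fields$cars, config),
              tpef = apply_noise(fields$tpef, config),
              shg = apply_noise(fields$shg, config),
              tile_row = tile_row, tile_col = tile_col, fov_id = fov_id)
  })
}

#' Generate a synthetic two-class cohort
#'
#' Builds `n_patients_matched` patients with both a tumor and a normal
#' sample (plus any single-sample patients), each sample holding
#' `tiles_per_sample` tiles on a near-square grid. Structure (IDs, grid,
#' counts) depends only on the config, not on the seed; rasters are
#' deterministic per seed.
#'
#' @param config A [synthetic_config()].
#' @return List of [sample_record()] objects.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  tiles <- config$tiles_per_sample
  g_rows <- max(1L, floor(sqrt(tiles)))
  g_cols <- as.integer(ceiling(tiles / g_rows))
  grid <- c(as.integer(g_rows), g_cols)

  plan <- list()
  pid <- 0
  add_patient <- function(classes) {
    pid <<- pid + 1
    plan[[length(plan) + 1]] <<- list(idx = pid,
                                      id = sprintf("P%02d", pid),
                                      classes = classes)
  }
  for (i in seq_len(config$n_patients_matched)) add_patient(c("normal", "tumor"))
  for (i in seq_len(config$n_tumor_only)) add_patient("tumor")
  for (i in seq_len(config$n_normal_only)) add_patient("normal")

  out <- list()
  for (p in plan) {
    for (cls in p$classes) {
      s_idx <- match(cls, c("normal", "tumor"))
      fovs <- lapply(seq_len(tiles) - 1L, function(t) {
        generate_fov(cls, config,
                     rng_seed = substream_seed(config$seed, p$idx, s_idx, t),
                     tile_row = t %/% g_cols, tile_col = t %% g_cols,
                     fov_id = sprintf("%s_%s_t%03d", p$id, cls, t))
      })
      out[[length(out) + 1]] <- sample_record(
        patient_id = p$id, sample_id = paste0(p$id, "_", cls),
        tissue_label = cls, fovs = fovs, grid_shape = grid)
    }
  }
  out
}

#' Generate a tile carrying a known acquisition artifact
#'
#' Starts from a clean synthetic tile and injects one artifact so QC
#' behavior can be exercised: `"hole"` places a contiguous near-zero
#' elliptical region (about 8% of the area, above the default hole
#' threshold but below the coverage threshold), `"border"` blanks about
#' 25% of the columns on one side, and `"saturation"` pins a disc of
#' about 3% of the area at the 16-bit maximum.
#'
#' @param kind `"hole"`, `"border"`, or `"saturation"`.
#' @param config A [synthetic_config()].
#' @param rng_seed Integer seed, defaults to the config seed.
#' @return A [fov_image()].
#' @export
generate_artifact_fov <- function(kind = c("hole", "border", "saturation"),
                                  config = synthetic_config(),
                                  rng_seed = config$seed) {
  kind <- match.arg(kind)
  base <- generate_fov("normal", config, rng_seed = rng_seed)
  nr <- nrow(base$cars); nc <- ncol(base$cars)
  withr::with_seed(rng_seed + 1L, {
    if (kind == "hole") {
      a <- 0.18 * nr
      b <- 0.08 * nr * nc / (pi * a)
      cy <- nr / 2 + stats::runif(1, -0.1, 0.1) * nr
      cx <- nc / 2 + stats::runif(1, -0.1, 0.1) * nc
      rowg <- matrix(seq_len(nr), nr, nc)
      colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      inside <- ((rowg - cy) / a)^2 + ((colg - cx) / b)^2 <= 1
      for (ch in c("cars", "tpef", "shg")) {
        base[[ch]][inside] <- stats::rpois(sum(inside), 60)
      }
    } else if (kind == "border") {
      cols <- seq_len(round(0.25 * nc))
      for (ch in c("cars", "tpef", "shg")) {
        base[[ch]][, cols] <- matrix(stats::rpois(nr * length(cols), 60),
                                     nr, length(cols))
      }
    } else {
      r <- sqrt(0.03 * nr * nc / pi)
      cy <- stats::runif(1, r + 1, nr - r); cx <- stats::runif(1, r + 1, nc - r)
      rowg <- matrix(seq_len(nr), nr, nc)
      colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      inside <- (rowg - cy)^2 + (colg - cx)^2 <= r^2
      base$cars[inside] <- 65535
    }
  })
  base
}
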