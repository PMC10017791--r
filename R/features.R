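CHANNELS <- c("cars", "tpef", "shg")
FIRST_ORDER <- c("mean", "sd", "kurtosis", "skewness", "entropy")
GLCM_STATS <- c("contrast", "correlation", "energy", "homogeneity")
ORIENTATIONS <- c(0, 45, 90, 135)

#' Define the texture parameters to extract
#'
#' A feature specification names, per channel, which first-order statistics
#' and which gray-level co-occurrence matrix (GLCM) statistics to compute,
#' together with the GLCM settings shared by all channels. The full
#' per-channel set is 5 first-order + 4 GLCM statistics x 3 distances = 17
#' parameters.
#'
#' Feature order is fixed: channels in the order CARS, TPEF, SHG; within a
#' channel the first-order statistics in the order mean, sd, kurtosis,
#' skewness, entropy, then one block per distance with GLCM statistics in
#' the order contrast, correlation, energy, homogeneity. Columns are named
#' `<channel>_<stat>` and `<channel>_<stat>_d<distance>`.
#'
#' @param channels Named list (names among `"cars"`, `"tpef"`, `"shg"`);
#'   each element a list with character vectors `first_order` (subset of
#'   mean, sd, kurtosis, skewness, entropy) and `glcm` (subset of contrast,
#'   correlation, energy, homogeneity). A channel absent from the list is
#'   excluded entirely.
#' @param distances Integer pixel offsets for the GLCM, default
#'   `c(1, 12, 30)` (at 1 um/pixel these are 1, 12 and 30 um).
#' @param levels Number of gray levels for GLCM quantization, default 8.
#' @param symmetric Count pixel pairs in both directions? Default `FALSE`.
#' @return An object of class `feature_spec`.
#' @seealso [feature_spec_full()], [feature_spec_selected()],
#'   [feature_spec_cars_only()]
#' @export
feature_spec <- function(channels, distances = c(1L, 12L, 30L),
                         levels = 8L, symmetric = FALSE) {
  stopifnot(is.list(channels), length(channels) >= 1)
  bad <- setdiff(names(channels), CHANNELS)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  channels <- channels[intersect(CHANNELS, names(channels))]
  channels <- lapply(channels, function(ch) {
    list(first_order = intersect(FIRST_ORDER, ch$first_order),
         glcm = intersect(GLCM_STATS, ch$glcm))
  })
  distances <- as.integer(distances)
  stopifnot(all(distances >= 1L), as.integer(levels) >= 2L)
  structure(
    list(channels = channels, distances = distances,
         levels = as.integer(levels), symmetric = isTRUE(symmetric)),
    class = "feature_spec"
  )
}

full_channel <- function() list(first_order = FIRST_ORDER, glcm = GLCM_STATS)

#' Canonical feature specifications
#'
#' `feature_spec_full()` uses all 17 parameters in each of the three
#' channels (51 features). `feature_spec_selected()` is the configuration
#' found best for tumor/normal liver discrimination: all 17 parameters of
#' CARS and TPEF but only 8 of SHG (the 5 first-order parameters plus
#' contrast at the three distances), 42 features in total.
#' `feature_spec_cars_only()` keeps the 17 CARS parameters alone, the
#' variant that remains usable when autofluorescence is perturbed.
#'
#' @inheritParams feature_spec
#' @return A `feature_spec`.
#' @export
feature_spec_full <- function(distances = c(1L, 12L, 30L), levels = 8L,
                              symmetric = FALSE) {
  feature_spec(list(cars = full_channel(), tpef = full_channel(),
                    shg = full_channel()),
               distances = distances, levels = levels, symmetric = symmetric)
}

#' @rdname feature_spec_full
#' @export
feature_spec_selected <- function(distances = c(1L, 12L, 30L), levels = 8L,
                                  symmetric = FALSE) {
  feature_spec(list(cars = full_channel(), tpef = full_channel(),
                    shg = list(first_order = FIRST_ORDER, glcm = "contrast")),
               distances = distances, levels = levels, symmetric = symmetric)
}

#' @rdname feature_spec_full
#' @export
feature_spec_cars_only <- function(distances = c(1L, 12L, 30L), levels = 8L,
                                   symmetric = FALSE) {
  feature_spec(list(cars = full_channel()),
               distances = distances, levels = levels, symmetric = symmetric)
}

#' Ordered feature column names of a specification
#'
#' @param spec A [feature_spec()].
#' @return Character vector of feature column names in extraction order.
#' @export
feature_names <- function(spec) {
  stopifnot(inherits(spec, "feature_spec"))
  unlist(lapply(names(spec$channels), function(chn) {
    ch <- spec$channels[[chn]]
    fo <- if (length(ch$first_order)) paste(chn, ch$first_order, sep = "_")
    so <- if (length(ch$glcm)) {
      unlist(lapply(spec$distances, function(d) {
        paste0(chn, "_", ch$glcm, "_d", d)
      }))
    }
    c(fo, so)
  }), use.names = FALSE)
}

#' @export
print.feature_spec <- function(x, ...) {
  per <- vapply(names(x$channels), function(chn) {
    ch <- x$channels[[chn]]
    length(ch$first_order) + length(ch$glcm) * length(x$distances)
  }, integer(1))
  cat(sprintf(
    "<feature_spec: %s; distances [%s], %d levels, %s; %d features>\n",
    paste(sprintf("%s=%d", names(per), per), collapse = " "),
    paste(x$distances, collapse = ","), x$levels,
    if (x$symmetric) "symmetric" else "asymmetric", sum(per)))
  invisible(x)
}

#' Min-max normalize an intensity raster to [0, 1]
#'
#' Applied per channel and per FoV before any texture statistic is
#' computed, so features are invariant to detector gain. A constant raster
#' has no range; it maps to all zeros and the result carries attribute
#' `degenerate = TRUE` (with a warning), keeping downstream features
#' finite.
#'
#' @param raster Numeric matrix of finite intensities.
#' @return Matrix with values in `[0, 1]` and attribute `degenerate`.
#' @export
normalize_channel <- function(raster) {
  stopifnot(is.matrix(raster), all(is.finite(raster)))
  rng <- range(raster)
  if (rng[1] == rng[2]) {
    warning("constant raster: min-max normalization is degenerate, returning zeros",
            call. = FALSE)
    out <- array(0, dim = dim(raster))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (raster - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' First-order texture statistics of a normalized raster
#'
#' Statistics of the pixel-intensity distribution, ignoring spatial
#' arrangement: mean, population standard deviation, kurtosis
#' (non-excess, `m4/m2^2`, so a Gaussian gives 3), skewness
#' (`m3/m2^1.5`), and Shannon entropy in bits of the 256-bin histogram on
#' `[0, 1]` (empty bins skipped). Skewness and kurtosis are defined as 0
#' for a zero-variance raster.
#'
#' @param raster Numeric matrix with values in `[0, 1]`.
#' @return Named numeric vector `(mean, sd, kurtosis, skewness, entropy)`.
#' @export
first_order_features <- function(raster) {
  x <- as.vector(raster)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    sk <- 0
    ku <- 0
  } else {
    sk <- mean((x - m)^3) / m2^1.5
    ku <- mean((x - m)^4) / m2^2
  }
  counts <- tabulate(pmin(floor(x * 256) + 1L, 256L), nbins = 256L)
  p <- counts[counts > 0] / length(x)
  ent <- -sum(p * log2(p))
  c(mean = m, sd = sqrt(m2), kurtosis = ku, skewness = sk, entropy = ent)
}

glcm_offset <- function(orientation, distance) {
  d <- as.integer(distance)
  switch(as.character(orientation),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("orientation must be one of 0, 45, 90, 135", call. = FALSE))
}

quantize_levels <- function(raster, levels) {
  # equal-width bins on [0,1]; the last bin is closed so 1.0 maps to `levels`
  pmin(floor(raster * levels) + 1L, levels)
}

#' Gray-level co-occurrence matrix
#'
#' Counts quantized pixel-value pairs `(p, p + offset)` at a given distance
#' and orientation, with orientation offsets (in `(row, col)` convention)
#' 0 deg -> `(0, +d)`, 45 deg -> `(-d, +d)`, 90 deg -> `(-d, 0)`,
#' 135 deg -> `(-d, -d)`. Values are quantized into `levels` equal-width
#' bins on `[0, 1]`; only pairs with both ends inside the raster are
#' counted; counts (mirrored first, if `symmetric`) are normalized to sum
#' to 1.
#'
#' @param raster Numeric matrix with values in `[0, 1]`.
#' @param distance Pixel offset, `>= 1`.
#' @param orientation One of `0`, `45`, `90`, `135` (degrees).
#' @param levels Number of gray levels (`>= 2`), default 8.
#' @param symmetric Count each pair in both directions? Default `FALSE`.
#' @return `levels` x `levels` probability matrix (rows: first pixel).
#' @export
glcm <- function(raster, distance, orientation, levels = 8L,
                 symmetric = FALSE) {
  stopifnot(is.matrix(raster), distance >= 1, levels >= 2)
  levels <- as.integer(levels)
  off <- glcm_offset(orientation, distance)
  nr <- nrow(raster); nc <- ncol(raster)
  rows <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  cols <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (rows[1] > rows[length(rows)] || cols[1] > cols[length(cols)] ||
      nr - abs(off[1]) < 1L || nc - abs(off[2]) < 1L) {
    stop("no valid pairs: distance exceeds raster extent", call. = FALSE)
  }
  q <- quantize_levels(raster, levels)
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + off[1], cols + off[2], drop = FALSE]
  counts <- tabulate(a + (b - 1L) * levels, nbins = levels * levels)
  P <- matrix(counts, levels, levels)
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

#' Second-order statistics of a co-occurrence matrix
#'
#' Computes contrast `sum P(i,j) (i-j)^2`, correlation
#' `sum P(i,j)(i - mu_r)(j - mu_c) / (sigma_r sigma_c)` (0 when either
#' marginal variance vanishes), energy `sum P(i,j)^2` (angular second
#' moment), and homogeneity `sum P(i,j) / (1 + |i-j|)`.
#'
#' @param P Square probability matrix summing to 1.
#' @return Named numeric `(contrast, correlation, energy, homogeneity)`.
#' @export
glcm_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) {
    stop("GLCM is not normalized (entries must sum to 1)", call. = FALSE)
  }
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pr <- rowSums(P); pc <- colSums(P)
  mu_r <- sum(seq_len(L) * pr); mu_c <- sum(seq_len(L) * pc)
  v_r <- sum((seq_len(L) - mu_r)^2 * pr)
  v_c <- sum((seq_len(L) - mu_c)^2 * pc)
  corr <- if (v_r * v_c > 0) {
    sum(P * (i - mu_r) * (j - mu_c)) / sqrt(v_r * v_c)
  } else 0
  c(contrast = sum(P * (i - j)^2),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))))
}

channel_features <- function(raster, ch, spec) {
  norm <- suppressWarnings(normalize_channel(raster))
  vals <- numeric(0)
  if (length(ch$first_order)) {
    fo <- first_order_features(norm)
    vals <- c(vals, fo[ch$first_order])
  }
  if (length(ch$glcm)) {
    for (d in spec$distances) {
      per_orient <- vapply(ORIENTATIONS, function(o) {
        glcm_features(glcm(norm, d, o, spec$levels, spec$symmetric))
      }, numeric(4))
      avg <- rowMeans(per_orient)   # plain arithmetic mean over orientations
      v <- avg[ch$glcm]
      names(v) <- paste0(ch$glcm, "_d", d)
      vals <- c(vals, v)
    }
  }
  vals
}

#' Extract texture features from FoVs
#'
#' For each channel requested by the specification: min-max normalize,
#' compute the requested first-order statistics, then for every distance
#' compute each GLCM statistic in the four orientations and report the
#' arithmetic mean over orientations. Channels are concatenated in the
#' order CARS, TPEF, SHG.
#'
#' @param x A [fov_image()], a [sample_record()], or a list of sample
#'   records (a cohort).
#' @param spec A [feature_spec()].
#' @param ... Unused.
#' @return A tibble with one row per FoV: provenance columns
#'   (`patient_id`, `sample_id`, `tissue_label`, `fov_id`, `tile_row`,
#'   `tile_col`, where known) followed by one column per feature, named
#'   and ordered per [feature_names()].
#' @export
extract_features <- function(x, spec = feature_spec_full(), ...) {
  UseMethod("extract_features")
}

fov_feature_row <- function(fov, spec) {
  vals <- unlist(lapply(names(spec$channels), function(chn) {
    v <- channel_features(fov[[chn]], spec$channels[[chn]], spec)
    names(v) <- paste(chn, names(v), sep = "_")
    v
  }))
  stopifnot(identical(names(vals), feature_names(spec)))
  tibble::as_tibble(as.list(vals))
}

#' @export
extract_features.fov_image <- function(x, spec = feature_spec_full(), ...) {
  dplyr::bind_cols(
    tibble::tibble(fov_id = x$fov_id, tile_row = x$tile_row,
                   tile_col = x$tile_col),
    fov_feature_row(x, spec)
  )
}

#' @export
extract_features.sample_record <- function(x, spec = feature_spec_full(), ...) {
  purrr::map_dfr(x$fovs, function(fov) {
    dplyr::bind_cols(
      tibble::tibble(patient_id = x$patient_id, sample_id = x$sample_id,
                     tissue_label = x$tissue_label, fov_id = fov$fov_id,
                     tile_row = fov$tile_row, tile_col = fov$tile_col),
      fov_feature_row(fov, spec)
    )
  })
}

#' @export
extract_features.list <- function(x, spec = feature_spec_full(), ...) {
  purrr::map_dfr(x, extract_features, spec = spec)
}
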