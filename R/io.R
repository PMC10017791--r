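#' Write a sample's FoV stack to disk
#'
#' Two plain layouts are supported, both with a `tiles.csv` sidecar (tile
#' id, row, col, file names) and a `meta.json` carrying sample identity,
#' grid shape, and the explicit channel order — channel assignment is
#' never guessed from pixel statistics. `"multitiff"` writes one 3-page
#' 16-bit TIFF per FoV (page order = channel order in `meta.json`);
#' `"perchannel"` writes one single-page 16-bit TIFF per channel per FoV.
#' Integer intensities in `[0, 65535]` round-trip losslessly.
#'
#' @param sample A [sample_record()] with at least one FoV.
#' @param path Directory to create/write into.
#' @param layout `"multitiff"` or `"perchannel"`.
#' @return `path`, invisibly.
#' @export
write_fov_stack <- function(sample, path, layout = c("multitiff", "perchannel")) {
  layout <- match.arg(layout)
  stopifnot(inherits(sample, "sample_record"))
  if (length(sample$fovs) == 0) stop("no FoVs to write", call. = FALSE)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    stop("cannot create directory ", path, call. = FALSE)
  }
  meta <- list(patient_id = sample$patient_id, sample_id = sample$sample_id,
               tissue_label = sample$tissue_label,
               grid_shape = sample$grid_shape, layout = layout,
               channels = CHANNELS, bits = 16L, max_intensity = 65535L)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- lapply(sample$fovs, function(f) {
    if (layout == "multitiff") {
      file <- paste0(f$fov_id, ".tif")
      tiff::writeTIFF(lapply(CHANNELS, function(ch) f[[ch]] / 65535),
                      file.path(path, file), bits.per.sample = 16L)
      tibble::tibble(fov_id = f$fov_id, tile_row = f$tile_row,
                     tile_col = f$tile_col, file = file)
    } else {
      files <- stats::setNames(paste0(f$fov_id, "_", CHANNELS, ".tif"),
                               CHANNELS)
      for (ch in CHANNELS) {
        tiff::writeTIFF(f[[ch]] / 65535, file.path(path, files[[ch]]),
                        bits.per.sample = 16L)
      }
      tibble::tibble(fov_id = f$fov_id, tile_row = f$tile_row,
                     tile_col = f$tile_col,
                     file_cars = files[["cars"]], file_tpef = files[["tpef"]],
                     file_shg = files[["shg"]])
    }
  })
  utils::write.csv(dplyr::bind_rows(rows), file.path(path, "tiles.csv"),
                   row.names = FALSE)
  invisible(path)
}

read_raster_16 <- function(file) {
  if (!file.exists(file)) return(NULL)
  round(tiff::readTIFF(file) * 65535)
}

#' Read a sample's FoV stack from disk
#'
#' Reads the layout written by [write_fov_stack()], using `meta.json` for
#' channel order and sample identity and `tiles.csv` for grid positions.
#'
#' @param path Directory containing `meta.json` and `tiles.csv`.
#' @param layout Optional layout override; defaults to the one recorded
#'   in `meta.json`.
#' @return A [sample_record()].
#' @export
read_fov_stack <- function(path, layout = NULL) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("no meta.json under ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  layout <- layout %||% meta$layout
  tiles <- utils::read.csv(file.path(path, "tiles.csv"),
                           stringsAsFactors = FALSE)
  fovs <- lapply(seq_len(nrow(tiles)), function(i) {
    row <- tiles[i, ]
    if (layout == "multitiff") {
      pages <- tiff::readTIFF(file.path(path, row$file), all = TRUE)
      if (length(pages) < length(meta$channels)) {
        missing <- meta$channels[seq(length(pages) + 1, length(meta$channels))]
        stop("missing channel ", toupper(missing[1]), " in ", row$file,
             call. = FALSE)
      }
      chans <- stats::setNames(lapply(pages[seq_along(meta$channels)],
                                      function(p) round(p * 65535)),
                               meta$channels)
    } else {
      chans <- lapply(stats::setNames(CHANNELS, CHANNELS), function(ch) {
        read_raster_16(file.path(path, row[[paste0("file_", ch)]]))
      })
      absent <- names(chans)[vapply(chans, is.null, logical(1))]
      if (length(absent)) {
        stop("missing channel ", toupper(absent[1]), " for FoV ",
             row$fov_id, call. = FALSE)
      }
    }
    fov_image(cars = chans$cars, tpef = chans$tpef, shg = chans$shg,
              tile_row = row$tile_row, tile_col = row$tile_col,
              fov_id = row$fov_id)
  })
  sample_record(patient_id = meta$patient_id, sample_id = meta$sample_id,
                tissue_label = meta$tissue_label, fovs = fovs,
                grid_shape = meta$grid_shape)
}

#' Write an RGB composite of one FoV
#'
#' Encodes the three channels as an 8-bit RGB image with the fixed
#' routing R = CARS, G = TPEF, B = SHG. Each channel is mapped through
#' `clip01(gain * x + offset)` and scaled to 0..255, mirroring the linear
#' per-channel contrast correction used for visualization.
#'
#' @param fov A [fov_image()].
#' @param path Output PNG file.
#' @param scale Named list with `(gain, offset)` per channel; default
#'   gain `1/65535`, offset 0 for each.
#' @return The `[0, 1]` RGB array, invisibly.
#' @export
write_composite <- function(fov, path,
                            scale = list(cars = c(1 / 65535, 0),
                                         tpef = c(1 / 65535, 0),
                                         shg = c(1 / 65535, 0))) {
  stopifnot(inherits(fov, "fov_image"))
  for (ch in CHANNELS) {
    if (is.null(scale[[ch]])) scale[[ch]] <- c(1 / 65535, 0)
    if (scale[[ch]][1] <= 0) stop("gain must be positive for channel ",
                                  toupper(ch), call. = FALSE)
  }
  img <- array(0, dim = c(nrow(fov$cars), ncol(fov$cars), 3))
  for (k in seq_along(CHANNELS)) {
    ch <- CHANNELS[k]
    img[, , k] <- clip01(scale[[ch]][1] * fov[[ch]] + scale[[ch]][2])
  }
  img <- round(img * 255) / 255
  png::writePNG(img, path)
  invisible(img)
}

#' Write / read a feature table as CSV
#'
#' One row per FoV; provenance columns first, then one column per named
#' feature in specification order.
#'
#' @param features Tibble from [extract_features()].
#' @param path CSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

spec_to_list <- function(spec) {
  list(channels = spec$channels, distances = spec$distances,
       levels = spec$levels, symmetric = spec$symmetric)
}

spec_from_list <- function(x) {
  feature_spec(lapply(x$channels, function(ch) {
    list(first_order = as.character(ch$first_order),
         glcm = as.character(ch$glcm))
  }), distances = x$distances, levels = x$levels, symmetric = x$symmetric)
}

#' Serialize / restore a discriminant model as JSON
#'
#' Numbers are written at full precision; the covariance inverse and
#' log-determinant are recomputed on load from the stored covariance, so
#' posteriors reproduce within floating tolerance.
#'
#' @param model A [fit_discriminant()] model.
#' @param path JSON file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` a
#'   `discriminant_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "discriminant_model"))
  doc <- list(model_type = model$model_type, classes = model$classes,
              priors = as.list(model$priors),
              priors_mode = model$priors_mode,
              feature_names = model$feature_names,
              n_per_class = as.list(model$n_per_class),
              ridge = if (is.null(model$ridge)) NULL else as.list(model$ridge),
              means = if (is.null(model$means)) NULL else
                unname(model$means),
              cov = if (is.null(model$cov)) NULL else
                lapply(model$cov, unname),
              spec = if (is.null(model$spec)) NULL else
                spec_to_list(model$spec))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(model_type = doc$model_type, classes = doc$classes,
                priors = unlist(doc$priors),
                priors_mode = doc$priors_mode,
                feature_names = doc$feature_names,
                n_per_class = unlist(doc$n_per_class),
                spec = if (length(doc$spec)) spec_from_list(doc$spec))
  if (doc$model_type != "prior") {
    means <- doc$means
    rownames(means) <- doc$classes; colnames(means) <- doc$feature_names
    model$means <- means
    covs <- doc$cov
    sis <- lapply(covs, stable_inverse)
    model$inv <- lapply(sis, `[[`, "inv")
    model$logdet <- vapply(sis, `[[`, numeric(1), "logdet")
    model$ridge <- unlist(doc$ridge)
  }
  structure(model, class = "discriminant_model")
}

#' Save / load a synthetic cohort configuration as JSON
#'
#' A cohort regenerated from the saved configuration is identical to the
#' original.
#'
#' @param config A [synthetic_config()].
#' @param path JSON file path.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` a `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_config(fov_shape = x$fov_shape,
                   n_patients_matched = x$n_patients_matched,
                   n_tumor_only = x$n_tumor_only,
                   n_normal_only = x$n_normal_only,
                   tiles_per_sample = x$tiles_per_sample,
                   separability = x$separability,
                   noise_model = x$noise_model, noise_scale = x$noise_scale,
                   motifs = as.list(x$motifs),
                   intensity_scale = x$intensity_scale, seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
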