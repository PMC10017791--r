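#' Construct a field-of-view image
#'
#' A field of view (FoV) is one acquired image tile: three co-registered
#' single-channel intensity rasters (CARS, TPEF, SHG) plus its position on
#' the sample's tile grid. The default acquisition geometry is 152 x 302
#' pixels at 1 um/pixel; any shape is accepted as long as the three
#' channels agree.
#'
#' @param cars,tpef,shg Numeric matrices of non-negative, finite
#'   intensities, all with identical dimensions. CARS highlights lipid-rich
#'   structures, TPEF endogenous fluorophores, SHG fibrillar collagen.
#' @param tile_row,tile_col 0-based integer grid indices (row-major,
#'   top-left origin).
#' @param fov_id Character identifier, unique within a sample.
#' @return An object of class `fov_image`.
#' @export
fov_image <- function(cars, tpef, shg, tile_row = 0L, tile_col = 0L,
                      fov_id = "fov") {
  chans <- list(cars = cars, tpef = tpef, shg = shg)
  for (nm in names(chans)) {
    x <- chans[[nm]]
    if (!is.matrix(x) || !is.numeric(x)) {
      stop("channel ", toupper(nm), " must be a numeric matrix", call. = FALSE)
    }
    if (!all(is.finite(x))) {
      stop("channel ", toupper(nm), " contains non-finite intensities",
           call. = FALSE)
    }
    if (any(x < 0)) {
      stop("channel ", toupper(nm), " contains negative intensities",
           call. = FALSE)
    }
  }
  if (!identical(dim(cars), dim(tpef)) || !identical(dim(cars), dim(shg))) {
    stop("channel rasters have mismatched shapes", call. = FALSE)
  }
  structure(
    list(cars = cars, tpef = tpef, shg = shg,
         tile_row = as.integer(tile_row), tile_col = as.integer(tile_col),
         fov_id = as.character(fov_id)),
    class = "fov_image"
  )
}

#' @export
print.fov_image <- function(x, ...) {
  cat(sprintf("<fov_image '%s' %dx%d px, tile (%d,%d)>\n",
              x$fov_id, nrow(x$cars), ncol(x$cars), x$tile_row, x$tile_col))
  invisible(x)
}

#' Construct a tissue sample record
#'
#' One tissue block of one patient: an ordered set of FoV tiles on a grid,
#' plus the sample-level ground-truth tissue label that applies to every
#' tile. A patient contributes up to two samples (one tumor, one normal).
#'
#' @param patient_id,sample_id Character identifiers.
#' @param tissue_label `"normal"` or `"tumor"`.
#' @param fovs List of [fov_image()] objects with distinct grid positions,
#'   all inside `grid_shape`.
#' @param grid_shape Integer `(rows, cols)` of the tile grid.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(patient_id, sample_id, tissue_label, fovs,
                          grid_shape) {
  tissue_label <- match.arg(tissue_label, c("normal", "tumor"))
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  if (length(fovs) > 0) {
    ok <- vapply(fovs, inherits, logical(1), "fov_image")
    if (!all(ok)) stop("fovs must all be fov_image objects", call. = FALSE)
    pos <- vapply(fovs, function(f) c(f$tile_row, f$tile_col), integer(2))
    if (any(pos[1, ] < 0 | pos[1, ] >= grid_shape[1]) ||
        any(pos[2, ] < 0 | pos[2, ] >= grid_shape[2])) {
      stop("FoV grid position outside grid_shape", call. = FALSE)
    }
    key <- paste(pos[1, ], pos[2, ])
    if (anyDuplicated(key)) {
      stop("duplicate grid position: (", key[duplicated(key)][1], ")",
           call. = FALSE)
    }
  }
  structure(
    list(patient_id = as.character(patient_id),
         sample_id = as.character(sample_id),
         tissue_label = tissue_label,
         fovs = fovs,
         grid_shape = grid_shape),
    class = "sample_record"
  )
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record '%s' patient '%s' [%s], %d FoVs on %dx%d grid>\n",
              x$sample_id, x$patient_id, x$tissue_label, length(x$fovs),
              x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

#' Tabulate the tiles of a sample or cohort
#'
#' @param x A `sample_record` or a list of them (a cohort).
#' @return A tibble with one row per FoV: `patient_id`, `sample_id`,
#'   `tissue_label`, `fov_id`, `tile_row`, `tile_col`.
#' @export
fov_table <- function(x) {
  samples <- if (inherits(x, "sample_record")) list(x) else x
  purrr::map_dfr(samples, function(s) {
    if (length(s$fovs) == 0) return(tibble::tibble())
    tibble::tibble(
      patient_id = s$patient_id,
      sample_id = s$sample_id,
      tissue_label = s$tissue_label,
      fov_id = vapply(s$fovs, `[[`, character(1), "fov_id"),
      tile_row = vapply(s$fovs, `[[`, integer(1), "tile_row"),
      tile_col = vapply(s$fovs, `[[`, integer(1), "tile_col")
    )
  })
}
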