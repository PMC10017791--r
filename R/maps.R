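MAP_PALETTE <- list(
  tumor = c(230, 120, 20),      # posterior 1
  mid = c(128, 128, 128),       # posterior 0.5
  normal = c(120, 180, 230),    # posterior 0
  discarded = c(60, 60, 60),
  absent = c(245, 245, 245)
)

#' Map posterior probabilities to the tile color scale
#'
#' Two-segment linear interpolation: light blue at tumor posterior 0,
#' mid gray at 0.5, orange at 1, rounded to 8-bit channels so the
#' endpoints are bit-exact.
#'
#' @param p Numeric vector of tumor posteriors in `[0, 1]`.
#' @return Integer matrix `length(p)` x 3 (R, G, B in 0..255).
#' @export
posterior_color <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  lo <- MAP_PALETTE$normal; mid <- MAP_PALETTE$mid; hi <- MAP_PALETTE$tumor
  out <- vapply(seq_along(lo), function(k) {
    ifelse(p <= 0.5,
           lo[k] + (mid[k] - lo[k]) * (p / 0.5),
           mid[k] + (hi[k] - mid[k]) * ((p - 0.5) / 0.5))
  }, numeric(length(p)))
  matrix(as.integer(round(out)), ncol = 3,
         dimnames = list(NULL, c("r", "g", "b")))
}

#' Assemble a tiled posterior-probability map
#'
#' Lays per-tile classification results and QC discards onto the sample's
#' tile grid. Classified cells are colored by the posterior scale of
#' [posterior_color()], discarded cells dark gray, grid positions without
#' a tile stay background. Rendering is a pure function of its inputs.
#'
#' @param results Tibble with `tile_row`, `tile_col`, `posterior_tumor`
#'   (e.g. from [classify_images()]).
#' @param discards Tibble with `tile_row`, `tile_col` (and optionally
#'   `reason`) from [filter_sample()]; may be `NULL` or empty.
#' @param grid_shape Integer `(rows, cols)`.
#' @return A tibble of class `probability_map`, one row per grid cell:
#'   `tile_row`, `tile_col`, `state` (`"classified"`, `"discarded"`,
#'   `"absent"`), `posterior_tumor` (NA unless classified), `r`, `g`,
#'   `b`. Grid shape is carried in attribute `grid_shape`.
#' @export
assemble_map <- function(results, discards, grid_shape) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1))
  if (is.null(discards)) {
    discards <- tibble::tibble(tile_row = integer(), tile_col = integer())
  }
  check_inside <- function(tb, what) {
    if (nrow(tb) == 0) return()
    if (any(tb$tile_row < 0 | tb$tile_row >= grid_shape[1] |
            tb$tile_col < 0 | tb$tile_col >= grid_shape[2])) {
      stop(what, " reference positions outside grid_shape", call. = FALSE)
    }
  }
  check_inside(results, "results"); check_inside(discards, "discards")
  rkey <- paste(results$tile_row, results$tile_col)
  dkey <- paste(discards$tile_row, discards$tile_col)
  if (anyDuplicated(rkey) || anyDuplicated(dkey)) {
    stop("duplicate grid position within results or discards", call. = FALSE)
  }
  clash <- intersect(rkey, dkey)
  if (length(clash)) {
    stop("position collision between a result and a discard at (",
         clash[1], ")", call. = FALSE)
  }
  grid <- tidyr::expand_grid(tile_row = seq_len(grid_shape[1]) - 1L,
                             tile_col = seq_len(grid_shape[2]) - 1L)
  gkey <- paste(grid$tile_row, grid$tile_col)
  grid$state <- "absent"
  grid$posterior_tumor <- NA_real_
  grid$state[gkey %in% dkey] <- "discarded"
  hit <- match(rkey, gkey)
  grid$state[hit] <- "classified"
  grid$posterior_tumor[hit] <- results$posterior_tumor
  cols <- matrix(rep(unlist(MAP_PALETTE$absent), each = nrow(grid)),
                 ncol = 3, dimnames = list(NULL, c("r", "g", "b")))
  disc <- grid$state == "discarded"
  if (any(disc)) {
    cols[disc, ] <- matrix(MAP_PALETTE$discarded, sum(disc), 3, byrow = TRUE)
  }
  cls <- grid$state == "classified"
  if (any(cls)) cols[cls, ] <- posterior_color(grid$posterior_tumor[cls])
  grid$r <- as.integer(cols[, 1]); grid$g <- as.integer(cols[, 2])
  grid$b <- as.integer(cols[, 3])
  structure(grid, class = c("probability_map", class(grid)),
            grid_shape = grid_shape)
}

#' Render a probability map as an RGB raster
#'
#' @param map A [assemble_map()] result.
#' @param tile_px Square block size per tile, default 8 pixels.
#' @return Numeric array `(rows*tile_px, cols*tile_px, 3)` in `[0, 1]`.
#' @export
render_map <- function(map, tile_px = 8L) {
  gs <- attr(map, "grid_shape")
  img <- array(0, dim = c(gs[1] * tile_px, gs[2] * tile_px, 3))
  for (i in seq_len(nrow(map))) {
    rr <- map$tile_row[i] * tile_px + seq_len(tile_px)
    cc <- map$tile_col[i] * tile_px + seq_len(tile_px)
    img[rr, cc, 1] <- map$r[i] / 255
    img[rr, cc, 2] <- map$g[i] / 255
    img[rr, cc, 3] <- map$b[i] / 255
  }
  img
}

#' Write a probability map as PNG plus CSV twin
#'
#' @param map A [assemble_map()] result.
#' @param png_path,csv_path Output paths (`NULL` skips one of them).
#' @param tile_px Block size per tile.
#' @return Invisible list of written paths.
#' @export
write_map <- function(map, png_path = NULL, csv_path = NULL, tile_px = 8L) {
  if (!is.null(png_path)) png::writePNG(render_map(map, tile_px), png_path)
  if (!is.null(csv_path)) {
    utils::write.csv(
      map[, c("tile_row", "tile_col", "state", "posterior_tumor")],
      csv_path, row.names = FALSE, na = "")
  }
  invisible(list(png = png_path, csv = csv_path))
}

#' Plot a probability map
#'
#' @param object A `probability_map`.
#' @param ... Unused.
#' @return A ggplot tile plot with the map color scale; the tile-row axis
#'   is reversed so the grid reads top-down like the acquisition.
#' @exportS3Method ggplot2::autoplot
autoplot.probability_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$fill <- grDevices::rgb(df$r, df$g, df$b, maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tile_col, y = .data$tile_row,
                                   fill = .data$fill)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "tile column", y = "tile row") +
    ggplot2::theme_minimal()
}
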