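#' Quality-control thresholds for tile screening
#'
#' Tiles containing tissue borders, large holes, or detector-saturation
#' artifacts must be excluded before feature extraction. The screening
#' rules are numeric reconstructions of that intent:
#' a pixel counts as foreground when its combined CARS + TPEF intensity
#' exceeds `foreground_intensity_fraction` of the single-channel full
#' scale (`max_intensity`); a tile is discarded when its saturated-pixel
#' fraction (any channel at `max_intensity` or above) exceeds
#' `max_saturated_fraction`, when its foreground coverage falls below
#' `min_coverage` (tissue borders), or when the largest 4-connected
#' background component exceeds `max_hole_fraction` of the tile area
#' (holes). SHG does not enter the foreground test because sparse SHG is
#' legitimate in normal liver.
#'
#' @param foreground_intensity_fraction Fraction of `max_intensity` above
#'   which the CARS + TPEF sum marks a foreground pixel. Default 0.05.
#' @param min_coverage Minimum foreground fraction to keep a tile.
#'   Default 0.90.
#' @param max_hole_fraction Maximum area fraction of the largest connected
#'   background component. Default 0.05.
#' @param max_saturated_fraction Maximum fraction of saturated pixels.
#'   Default 0.01.
#' @param max_intensity Full-scale intensity of one channel (16-bit
#'   default, 65535).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(foreground_intensity_fraction = 0.05,
                          min_coverage = 0.90,
                          max_hole_fraction = 0.05,
                          max_saturated_fraction = 0.01,
                          max_intensity = 65535) {
  fr <- c(foreground_intensity_fraction, min_coverage, max_hole_fraction,
          max_saturated_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1), max_intensity > 0)
  structure(
    list(foreground_intensity_fraction = foreground_intensity_fraction,
         min_coverage = min_coverage,
         max_hole_fraction = max_hole_fraction,
         max_saturated_fraction = max_saturated_fraction,
         max_intensity = max_intensity),
    class = "qc_thresholds"
  )
}

largest_background_fraction <- function(background) {
  if (!any(background)) return(0)
  lab <- EBImage::bwlabel(matrix(as.numeric(background),
                                 nrow(background), ncol(background)))
  max(tabulate(as.integer(lab))) / length(background)
}

#' Assess one tile against the QC rules
#'
#' Deterministic screening; the failure reasons are evaluated in the fixed
#' order saturation, low coverage, hole, and the first failure is
#' reported.
#'
#' @param fov A [fov_image()].
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_status` with fields `keep` (logical) and
#'   `reason` (`"ok"`, `"saturation"`, `"low_coverage"`, or `"hole"`);
#'   `keep` is `TRUE` iff `reason == "ok"`.
#' @export
assess_fov <- function(fov, thresholds = qc_thresholds()) {
  stopifnot(inherits(fov, "fov_image"), inherits(thresholds, "qc_thresholds"))
  mx <- thresholds$max_intensity
  sat <- mean(fov$cars >= mx | fov$tpef >= mx | fov$shg >= mx)
  if (sat > thresholds$max_saturated_fraction) {
    return(qc_status(FALSE, "saturation"))
  }
  fg <- (fov$cars + fov$tpef) > thresholds$foreground_intensity_fraction * mx
  coverage <- mean(fg)
  if (coverage < thresholds$min_coverage) {
    return(qc_status(FALSE, "low_coverage"))
  }
  # a cheap bound: the largest component cannot exceed total background
  if (1 - coverage > thresholds$max_hole_fraction &&
      largest_background_fraction(!fg) > thresholds$max_hole_fraction) {
    return(qc_status(FALSE, "hole"))
  }
  qc_status(TRUE, "ok")
}

qc_status <- function(keep, reason) {
  structure(list(keep = keep, reason = reason), class = "qc_status")
}

#' @export
print.qc_status <- function(x, ...) {
  cat(sprintf("<qc_status %s (%s)>\n", if (x$keep) "keep" else "discard",
              x$reason))
  invisible(x)
}

#' Screen every tile of a sample
#'
#' @param sample A [sample_record()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with `kept` (a `sample_record` containing only passing
#'   tiles, grid positions preserved) and `discards` (tibble with columns
#'   `fov_id`, `tile_row`, `tile_col`, `reason`, one row per discarded
#'   tile), suitable for dark-gray slots in probability maps.
#' @export
filter_sample <- function(sample, thresholds = qc_thresholds()) {
  stopifnot(inherits(sample, "sample_record"))
  status <- lapply(sample$fovs, assess_fov, thresholds = thresholds)
  keep <- vapply(status, `[[`, logical(1), "keep")
  discards <- purrr::map_dfr(which(!keep), function(i) {
    f <- sample$fovs[[i]]
    tibble::tibble(fov_id = f$fov_id, tile_row = f$tile_row,
                   tile_col = f$tile_col, reason = status[[i]]$reason)
  })
  if (nrow(discards) == 0) {
    discards <- tibble::tibble(fov_id = character(), tile_row = integer(),
                               tile_col = integer(), reason = character())
  }
  kept <- sample
  kept$fovs <- sample$fovs[keep]
  list(kept = kept, discards = discards)
}
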