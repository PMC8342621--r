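# Tumor proportion scoring: label nucleus points with the tumor and positive
# masks, count N_tt and N_pt, and map the TPS to the 3-level expression class.
#
# TPS(%) = 100 * (# PD-L1 positive tumor cells) / (# viable tumor cells),
# with levels negative (< 1%), low (1-49%), high (>= 50%).

#' Label nucleus points using the tumor and positive-stain masks
#'
#' A point is a tumor cell iff the tumor mask is set at its (scaled) location;
#' a tumor cell is PD-L1 positive iff any positive-stain pixel lies within a
#' disc of radius `rho` around its centre (membrane staining surrounds the
#' nucleus rather than covering it). Non-tumor points are never positive.
#' Coordinates are mapped between magnifications by integer floor division
#' (points at 40x, tumor mask typically at 20x: factor 2).
#'
#' @param points Tibble with `x`, `y` at 40x (0-based).
#' @param tumor_mask Binary tumor mask tagged with its magnification
#'   ([as_mask()]); typically 20x.
#' @param positive_mask Binary positive-stain mask tagged with its
#'   magnification; typically 40x.
#' @param rho Scoring-disc radius in px at 40x (default 8).
#' @return `points` with `is_tumor`, `is_positive` replaced by mask-derived
#'   labels.
#' @export
classify_nuclei <- function(points, tumor_mask, positive_mask, rho = 8) {
  points <- tibble::as_tibble(points)
  mag_t <- mask_magnification(tumor_mask)
  mag_p <- mask_magnification(positive_mask)
  if (nrow(points) == 0) {
    points$is_tumor <- logical(0); points$is_positive <- logical(0)
    return(points)
  }
  ft <- 40 / mag_t
  tx <- floor(points$x / ft); ty <- floor(points$y / ft)
  tx <- clamp(tx, 0, ncol(tumor_mask) - 1); ty <- clamp(ty, 0, nrow(tumor_mask) - 1)
  is_tumor <- tumor_mask[cbind(ty + 1, tx + 1)] > 0

  fp <- 40 / mag_p
  rho_p <- max(1, round(rho / fp))
  # dilating the positive mask by the scoring disc turns "any positive pixel
  # within rho" into a single-pixel lookup; the kernel is the exact Euclidean
  # disc (dx^2 + dy^2 <= rho^2)
  off <- seq(-rho_p, rho_p)
  disc <- outer(off, off, function(a, b) (a^2 + b^2 <= rho_p^2) + 0)
  dil <- EBImage::dilate((positive_mask > 0) + 0, disc)
  px <- clamp(floor(points$x / fp), 0, ncol(positive_mask) - 1)
  py <- clamp(floor(points$y / fp), 0, nrow(positive_mask) - 1)
  near_pos <- dil[cbind(py + 1, px + 1)] > 0
  points$is_tumor <- is_tumor
  points$is_positive <- is_tumor & near_pos
  points
}

#' Compute the tumor proportion score
#'
#' `TPS(%) = 100 * n_pt / n_tt`. A slide with no viable tumor cells cannot be
#' scored and raises an "insufficient viable tumor cells" error.
#'
#' @param n_pt Number of PD-L1-positive tumor cells (0 <= n_pt <= n_tt).
#' @param n_tt Number of viable tumor cells.
#' @return TPS percentage in `[0, 100]`.
#' @export
compute_tps <- function(n_pt, n_tt) {
  assert_that(n_tt >= 0 && n_pt >= 0 && n_pt <= n_tt,
              "require 0 <= n_pt <= n_tt")
  if (n_tt == 0)
    abort("insufficient viable tumor cells (n_tt = 0)",
          class = "pdl1tps_no_tumor_error")
  100 * n_pt / n_tt
}

#' Map TPS percentages to 3-level expression classes
#'
#' `< 1` -> negative, `[1, 50)` -> low, `>= 50` -> high; vectorized.
#'
#' @param tps_percent Numeric vector in `[0, 100]`.
#' @return Factor with levels negative, low, high.
#' @export
expression_level <- function(tps_percent) {
  assert_that(all(tps_percent >= 0 & tps_percent <= 100),
              "tps_percent must lie in [0, 100]")
  lv <- ifelse(tps_percent < 1, "negative", ifelse(tps_percent < 50, "low", "high"))
  factor(lv, levels = c("negative", "low", "high"))
}

#' Aggregate per-tile counts into a slide-level TPS result
#'
#' Counts are summed over tiles before the ratio is taken (cell-weighted, not
#' tile-averaged), so tiles with many cells weigh accordingly.
#'
#' @param tiles Data frame with columns `n_pt` and `n_tt` (one row per tile);
#'   extra columns are carried through in the breakdown.
#' @return A `tps_result`: `n_pt`, `n_tt`, `tps_percent`, `expression_level`,
#'   `tiles`.
#' @export
score_slide <- function(tiles) {
  tiles <- tibble::as_tibble(tiles)
  assert_that(all(c("n_pt", "n_tt") %in% names(tiles)),
              "tiles must have n_pt and n_tt columns")
  assert_that(all(tiles$n_pt <= tiles$n_tt),
              "n_pt must not exceed n_tt in any tile")
  n_pt <- sum(tiles$n_pt)
  n_tt <- sum(tiles$n_tt)
  tps <- compute_tps(n_pt, n_tt)
  structure(list(n_pt = n_pt, n_tt = n_tt, tps_percent = tps,
                 expression_level = expression_level(tps), tiles = tiles),
            class = "tps_result")
}

#' Score labelled nucleus points directly
#'
#' Convenience wrapper: counts tumor and positive-tumor points (e.g. the
#' output of [classify_nuclei()]) as a single tile and returns the
#' `tps_result`.
#'
#' @param points Tibble with logical `is_tumor`, `is_positive` columns.
#' @return A `tps_result`.
#' @export
score_points <- function(points) {
  score_slide(tibble::tibble(
    n_pt = sum(points$is_tumor & points$is_positive),
    n_tt = sum(points$is_tumor)))
}

#' @export
print.tps_result <- function(x, ...) {
  cat(sprintf("<tps_result> N_pt %d / N_tt %d -> TPS %.2f%% (%s), %d tile(s)\n",
              x$n_pt, x$n_tt, x$tps_percent, as.character(x$expression_level),
              nrow(x$tiles)))
  invisible(x)
}

#' @export
tidy.tps_result <- function(x, ...) x$tiles

#' @export
glance.tps_result <- function(x, ...) {
  tibble::tibble(n_pt = x$n_pt, n_tt = x$n_tt, tps_percent = x$tps_percent,
                 expression_level = as.character(x$expression_level),
                 n_tiles = nrow(x$tiles))
}
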