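# Unsupervised PD-L1 positive-membrane detection on the DAB plane.
#
# Pipeline: colour deconvolution -> difference-of-Gaussians band-pass (gates
# candidates to membrane-scale structure) -> luminance-adaptive
# multi-thresholding (block-local percentile thresholds) -> luminance-weighted
# thresholding on the original RGB -> morphological cleanup.

#' Sampled Gaussian kernels
#'
#' `gaussian_kernel()` returns a 1-D Gaussian sampled at integer offsets and
#' normalized to sum 1; `gaussian_kernel2d()` its separable 2-D outer product.
#' Kernels are truncated at `radius = ceiling(4 * sigma)`.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param radius Half-width in pixels; default `ceiling(4 * sigma)`.
#' @return Numeric vector (1-D) or matrix (2-D) summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  assert_that(sigma > 0, "sigma must be > 0", class = "pdl1tps_param_error")
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' @rdname gaussian_kernel
#' @export
gaussian_kernel2d <- function(sigma, radius = ceiling(4 * sigma)) {
  k <- gaussian_kernel(sigma, radius)
  outer(k, k)
}

#' Membrane-detection parameters
#'
#' Defaults are tuned for tiles at 40x (0.2375 um/px), where a stained
#' membrane is roughly 2-4 px thick: a narrow/wide Gaussian pair bracketing
#' that scale, 64-px LAMT blocks with five percentile candidates, and small
#' opening/closing radii.
#'
#' @param sigma_narrow,sigma_wide DoG Gaussian sigmas in px (`sigma_narrow <
#'   sigma_wide`).
#' @param lamt_block Side of the square LAMT window in px (>= 8).
#' @param lamt_levels Number of candidate percentile thresholds per block.
#' @param luminance_threshold Minimum darkness `1 - Y` (Rec. 601 luma) a
#'   candidate pixel must reach to stay positive, in `[0, 1]`.
#' @param min_dab Absolute floor (OD units) under the block-local LAMT
#'   thresholds; block quantiles are scale-free, so without a floor a DAB-free
#'   tile would mark noise.
#' @param open_radius,close_radius Disc structuring-element radii in px.
#' @param max_hole_area Holes up to this area (px) are filled.
#' @param min_object_area Connected components smaller than this are dropped.
#' @return A `membrane_params` list.
#' @export
membrane_params <- function(sigma_narrow = 1, sigma_wide = 2,
                            lamt_block = 64, lamt_levels = 5,
                            luminance_threshold = 0.25, min_dab = 0.15,
                            open_radius = 1, close_radius = 2,
                            max_hole_area = 50, min_object_area = 20) {
  assert_that(sigma_narrow > 0 && sigma_wide > 0 && sigma_narrow < sigma_wide,
              "require 0 < sigma_narrow < sigma_wide",
              class = "pdl1tps_param_error")
  assert_that(lamt_block >= 8, "lamt_block must be >= 8",
              class = "pdl1tps_param_error")
  assert_that(lamt_levels >= 1, "lamt_levels must be >= 1",
              class = "pdl1tps_param_error")
  assert_that(luminance_threshold >= 0 && luminance_threshold <= 1,
              "luminance_threshold must be in [0, 1]",
              class = "pdl1tps_param_error")
  assert_that(open_radius >= 0 && close_radius >= 0 &&
                max_hole_area >= 0 && min_object_area >= 0,
              "radii and areas must be >= 0", class = "pdl1tps_param_error")
  assert_that(min_dab >= 0, "min_dab must be >= 0", class = "pdl1tps_param_error")
  structure(list(sigma_narrow = sigma_narrow, sigma_wide = sigma_wide,
                 lamt_block = lamt_block, lamt_levels = lamt_levels,
                 luminance_threshold = luminance_threshold, min_dab = min_dab,
                 open_radius = open_radius, close_radius = close_radius,
                 max_hole_area = max_hole_area,
                 min_object_area = min_object_area),
            class = "membrane_params")
}

filter2_replicate <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}

#' Difference-of-Gaussians band-pass filter
#'
#' `G(sigma_narrow) * I - G(sigma_wide) * I` with replicate boundary handling.
#' Constant images map to (numerically) zero; thin bright ridges at the
#' membrane scale respond more strongly than wide plateaus of equal height.
#'
#' @param img Numeric matrix (typically the DAB concentration plane).
#' @param sigma_narrow,sigma_wide Gaussian sigmas in px, narrow < wide.
#' @return Matrix of band-pass responses (same size as `img`).
#' @export
dog_filter <- function(img, sigma_narrow = 1, sigma_wide = 2) {
  assert_that(sigma_narrow > 0 && sigma_wide > 0,
              "sigma must be > 0", class = "pdl1tps_param_error")
  assert_that(sigma_narrow < sigma_wide,
              "sigma_narrow must be < sigma_wide", class = "pdl1tps_param_error")
  kn <- gaussian_kernel2d(sigma_narrow)
  kw <- gaussian_kernel2d(sigma_wide)
  filter2_replicate(img, kn) - filter2_replicate(img, kw)
}

lamt_block_index <- function(n, block) {
  ((seq_len(n) - 1L) %/% block) + 1L
}

#' Luminance-adaptive multi-thresholding (LAMT)
#'
#' Tiles the DAB plane into `lamt_block`-sized square blocks (trailing blocks
#' may be smaller) and thresholds each block at one of `lamt_levels` candidate
#' percentiles (equally spaced from the 50th to the 90th) of the block's DAB
#' values. The middle candidate is the default; blocks whose mean luminance is
#' below the global mean (strongly stained neighbourhoods) shift one step
#' darker, i.e. to the next higher percentile. A pixel is a candidate iff its
#' DAB value strictly exceeds `max(selected block threshold, min_dab)`.
#'
#' @param dab_plane Non-negative DAB concentration matrix.
#' @param params [membrane_params()].
#' @param luminance Optional matrix of per-pixel luminance in `[0, 1]` used for
#'   the block adaptation; if `NULL` no shift is applied.
#' @return Binary candidate matrix.
#' @export
lamt_classify <- function(dab_plane, params = membrane_params(),
                          luminance = NULL) {
  assert_that(is.matrix(dab_plane) && all(dab_plane >= 0),
              "dab_plane must be a non-negative matrix")
  h <- nrow(dab_plane); w <- ncol(dab_plane)
  block <- params$lamt_block
  if (block > h && block > w) {
    warn("LAMT block larger than image; falling back to one global block")
    block <- max(h, w)
  }
  probs <- seq(0.5, 0.9, length.out = params$lamt_levels)
  base_idx <- ceiling(params$lamt_levels / 2)
  ri <- lamt_block_index(h, block)
  ci <- lamt_block_index(w, block)
  glob_lum <- if (!is.null(luminance)) mean(luminance) else NA_real_
  out <- matrix(0, h, w)
  for (bi in unique(ri)) {
    rows <- which(ri == bi)
    for (bj in unique(ci)) {
      cols <- which(ci == bj)
      vals <- dab_plane[rows, cols]
      idx <- base_idx
      if (!is.null(luminance) && mean(luminance[rows, cols]) < glob_lum)
        idx <- min(idx + 1L, params$lamt_levels)
      thr <- max(quantile(vals, probs[idx], names = FALSE), params$min_dab)
      out[rows, cols] <- (vals > thr) + 0
    }
  }
  out
}

#' Rec. 601 luminance of an RGB tile
#'
#' `(0.299 R + 0.587 G + 0.114 B) / 255`, in `[0, 1]`.
#'
#' @param rgb H x W x 3 array on the 0..255 scale.
#' @return Luminance matrix.
#' @export
luminance601 <- function(rgb) {
  check_rgb(rgb)
  (0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]) / 255
}

#' Luminance-weighted thresholding of candidate pixels
#'
#' Candidate positive pixels keep their status only if they are dark enough in
#' the original RGB image: darkness `1 - Y` (Y = Rec. 601 luminance) must reach
#' `luminance_threshold`. Pure-white candidates are always removed; near-black
#' candidates survive any threshold <= 1.
#'
#' @param candidates Binary matrix of candidate pixels.
#' @param rgb_tile H x W x 3 RGB array aligned with `candidates`.
#' @param luminance_threshold Darkness cut-off in `[0, 1]`.
#' @return Refined binary matrix.
#' @export
luminance_weighted_threshold <- function(candidates, rgb_tile,
                                         luminance_threshold = 0.25) {
  check_rgb(rgb_tile)
  assert_that(all(dim(candidates) == dim(rgb_tile)[1:2]),
              "candidates must align with rgb_tile")
  darkness <- 1 - luminance601(rgb_tile)
  ((candidates > 0) & (darkness >= luminance_threshold)) + 0
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

fill_small_holes <- function(mask, max_area) {
  if (max_area <= 0) return(mask)
  inv <- 1 - mask
  lab <- EBImage::bwlabel(inv)
  if (max(lab) == 0) return(mask)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  fill <- setdiff(which(areas > 0 & areas <= max_area), border_labels)
  if (length(fill)) mask[lab %in% fill] <- 1
  mask
}

drop_small_objects <- function(mask, min_area) {
  if (min_area <= 0 || !any(mask > 0)) return(mask)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(areas < min_area)
  if (length(drop)) mask[lab %in% drop] <- 0
  mask
}

#' Morphological cleanup of a positive-stain mask
#'
#' Opening (removes dot noise), closing (seals small membrane gaps), filling
#' of enclosed holes up to `max_hole_area`, then removal of connected
#' components below `min_object_area`. Idempotent: applying it twice equals
#' applying it once.
#'
#' @param mask Binary matrix.
#' @param params [membrane_params()].
#' @return Cleaned binary matrix.
#' @export
postprocess_mask <- function(mask, params = membrane_params()) {
  assert_that(is_binary_raster(mask * 1), "mask must be binary")
  m <- (mask > 0) + 0
  if (params$open_radius > 0)
    m <- EBImage::opening(m, disc_brush(params$open_radius))
  if (params$close_radius > 0)
    m <- EBImage::closing(m, disc_brush(params$close_radius))
  m <- fill_small_holes(m, params$max_hole_area)
  m <- drop_small_objects(m, params$min_object_area)
  m <- (m > 0) + 0
  m
}

#' Detect PD-L1-positive membrane pixels in an RGB tile
#'
#' Deterministic composition of the unsupervised positive-membrane detector:
#' colour deconvolution to the DAB plane, rectified DoG band-pass as a
#' membrane-scale gate, LAMT candidate classification, luminance-weighted
#' thresholding against the original RGB, and morphological cleanup.
#'
#' @param rgb_tile H x W x 3 RGB array on the 0..255 scale.
#' @param stains [stain_model()].
#' @param params [membrane_params()].
#' @param magnification Magnification tag recorded on the output mask.
#' @return Binary positive-stain mask (class `ihc_mask`) aligned with the tile.
#' @export
detect_positive_membrane <- function(rgb_tile, stains = stain_model(),
                                     params = membrane_params(),
                                     magnification = 40) {
  check_rgb(rgb_tile)
  od <- rgb_to_od(rgb_tile, stains$background_intensity)
  conc <- deconvolve(od, stains)
  dab <- conc[, , 2]
  dog <- dog_filter(dab, params$sigma_narrow, params$sigma_wide)
  gate <- (dog > 0)
  lum <- luminance601(rgb_tile)
  cand <- lamt_classify(dab, params, luminance = lum) * gate
  refined <- luminance_weighted_threshold(cand, rgb_tile,
                                          params$luminance_threshold)
  as_mask(postprocess_mask(refined, params), magnification)
}
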