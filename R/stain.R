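# Beer-Lambert stain model and colour deconvolution for H-DAB IHC.
#
# Stain amounts add linearly in optical density OD = -log10(I / I0); a 3x3
# matrix of unit-norm stain OD vectors (hematoxylin, DAB, residual) maps
# per-pixel concentration triplets to OD triplets. Deconvolution inverts it.

#' Construct an H-DAB stain model
#'
#' Holds the optical-density vectors used both to unmix RGB images into
#' hematoxylin / DAB / residual concentration planes and to render synthetic
#' images forward. Defaults are the standard published H-DAB vectors
#' (Ruifrok-Johnston); the residual vector defaults to the normalized cross
#' product of the other two, giving an orthogonal complement.
#'
#' @param hematoxylin,dab Length-3 non-negative OD vectors (will be normalized
#'   to unit Euclidean norm).
#' @param residual Optional length-3 OD vector; default cross product.
#' @param background_intensity Per-channel white level `I0` in `[1, 255]`.
#' @return An object of class `stain_model` with fields `vectors` (3x3 matrix,
#'   rows = stains, columns = R,G,B) and `background_intensity`.
#' @examples
#' sm <- stain_model()
#' rowSums(sm$vectors^2)  # unit norms
#' @export
stain_model <- function(hematoxylin = c(0.650, 0.704, 0.286),
                        dab = c(0.269, 0.568, 0.872),
                        residual = NULL,
                        background_intensity = c(255, 255, 255)) {
  norm1 <- function(v, nonneg = TRUE) {
    assert_that(length(v) == 3 && all(is.finite(v)),
                "stain vectors must have 3 finite components")
    if (nonneg)
      assert_that(all(v >= 0), "stain vector components must be >= 0")
    n <- sqrt(sum(v^2))
    assert_that(n > 0, "stain vector must be non-zero")
    v / n
  }
  h <- norm1(hematoxylin)
  d <- norm1(dab)
  if (is.null(residual)) {
    # classical complement: per-component sqrt(1 - h^2 - d^2); non-negative,
    # so rendered images stay inside the non-negative OD cone
    residual <- sqrt(pmax(0, 1 - h^2 - d^2))
  }
  r <- norm1(residual)
  M <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(M) <- c("R", "G", "B")
  assert_that(all(abs(sqrt(rowSums(M^2)) - 1) < 1e-6), "stain vectors not unit norm")
  rc <- rcond(M)
  assert_that(is.finite(rc) && rc > 1e-12,
              "stain matrix is singular; vectors must be linearly independent",
              class = "pdl1tps_config_error")
  if (length(background_intensity) == 1) background_intensity <- rep(background_intensity, 3)
  assert_that(all(background_intensity >= 1 & background_intensity <= 255),
              "background_intensity must lie in [1, 255]")
  structure(list(vectors = M, background_intensity = background_intensity),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model> OD vectors (rows = stains):\n")
  print(round(x$vectors, 4))
  cat("background intensity:", paste(x$background_intensity, collapse = ", "), "\n")
  invisible(x)
}

check_rgb <- function(rgb) {
  assert_that(is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] == 3,
              "input must be an H x W x 3 RGB array",
              class = "pdl1tps_format_error")
}

#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert transform `OD = -log10(max(I, eps * I0) / I0)`
#' per channel. Background (white) pixels map to OD ~ 0; darker pixels to
#' larger OD. Intensities are clamped below at `eps * I0` so the log is finite.
#'
#' @param rgb H x W x 3 array of intensities on the 0..255 scale (integer or
#'   float).
#' @param background_intensity Per-channel white level; scalar or length 3.
#' @param eps Clamp fraction of `I0` (default 1/255).
#' @return H x W x 3 array of optical densities (class `od_image`), with the
#'   background intensity stored as an attribute.
#' @export
rgb_to_od <- function(rgb, background_intensity = 255, eps = 1 / 255) {
  check_rgb(rgb)
  assert_that(all(background_intensity > 0), "background_intensity must be > 0")
  if (length(background_intensity) == 1) background_intensity <- rep(background_intensity, 3)
  od <- array(0, dim(rgb))
  for (c in 1:3) {
    i0 <- background_intensity[c]
    od[, , c] <- -log10(pmax(rgb[, , c], eps * i0) / i0)
  }
  od[od < 0] <- 0
  structure(od, background_intensity = background_intensity, class = "od_image")
}

#' Unmix an optical-density image into stain concentration planes
#'
#' Multiplies each OD pixel vector by the inverse of the stain matrix,
#' yielding per-stain concentration planes in the order hematoxylin, DAB,
#' residual. Negative concentrations (pixels outside the stain simplex) are
#' clamped to zero unless `clamp = FALSE`.
#'
#' @param od `od_image` or plain H x W x 3 OD array.
#' @param stains A [stain_model()].
#' @param clamp Clamp negative concentrations to 0 (default `TRUE`).
#' @return H x W x 3 concentration array; third dimension ordered
#'   (hematoxylin, dab, residual).
#' @export
deconvolve <- function(od, stains = stain_model(), clamp = TRUE) {
  assert_that(inherits(stains, "stain_model"), "stains must be a stain_model",
              class = "pdl1tps_config_error")
  d <- dim(od)
  assert_that(length(d) == 3 && d[3] == 3, "od must be an H x W x 3 array",
              class = "pdl1tps_format_error")
  Minv <- solve(stains$vectors)
  flat <- matrix(od, ncol = 3) %*% Minv
  if (clamp) flat[flat < 0] <- 0
  conc <- array(flat, d)
  attr(conc, "stains") <- rownames(stains$vectors)
  conc
}

#' Render stain concentrations back to an RGB image
#'
#' The forward Beer-Lambert model: `I = I0 * 10^-(C %*% M)` where `C` holds
#' per-pixel concentrations and `M` the stain OD vectors. Used by the
#' synthetic generator and as the inverse of [deconvolve()] in round-trip
#' checks.
#'
#' @param concentrations H x W x 3 non-negative array ordered
#'   (hematoxylin, dab, residual).
#' @param stains A [stain_model()].
#' @param quantize If `TRUE`, clip to `[0, 255]` and round to integers.
#' @return H x W x 3 RGB array on the 0..255 scale.
#' @export
od_to_rgb <- function(concentrations, stains = stain_model(), quantize = FALSE) {
  d <- dim(concentrations)
  assert_that(length(d) == 3 && d[3] == 3,
              "concentrations must be an H x W x 3 array",
              class = "pdl1tps_format_error")
  od <- matrix(concentrations, ncol = 3) %*% stains$vectors
  rgb <- array(0, d)
  for (c in 1:3) {
    rgb[, , c] <- stains$background_intensity[c] * 10^(-matrix(od[, c], d[1], d[2]))
  }
  if (quantize) rgb <- round(clamp(rgb, 0, 255))
  rgb
}
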