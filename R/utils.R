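# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg, class = "pdl1tps_error") {
  if (!isTRUE(cond)) abort(msg, class = class)
}

# Run code with a temporarily-seeded RNG, restoring global state afterwards.
# All stochastic entry points thread an explicit seed through this.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary_raster <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}

#' Tag a binary raster with its magnification
#'
#' Masks produced at different pyramid levels (tumor masks at 20x, positive
#' stain masks at 40x) carry a magnification attribute so that coordinate
#' mapping between levels is explicit rather than guessed.
#'
#' @param mask Binary matrix (rows = y, columns = x).
#' @param magnification Numeric objective magnification, e.g. `20` or `40`.
#' @return The mask with a `magnification` attribute, class `ihc_mask`.
#' @export
as_mask <- function(mask, magnification) {
  assert_that(is.matrix(mask), "mask must be a matrix")
  mask <- (mask > 0) + 0
  attr(mask, "magnification") <- magnification
  class(mask) <- c("ihc_mask", class(mask))
  mask
}

mask_magnification <- function(mask) {
  m <- attr(mask, "magnification")
  assert_that(!is.null(m),
              "mask has no magnification tag; use as_mask()",
              class = "pdl1tps_contract_error")
  m
}

# 2x block-mean downsampling of a matrix (H and W must be even).
downsample2_mean <- function(m) {
  h <- nrow(m) %/% 2L; w <- ncol(m) %/% 2L
  m <- m[seq_len(2L * h), seq_len(2L * w), drop = FALSE]
  0.25 * (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE] +
          m[seq(2, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE] +
          m[seq(1, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE] +
          m[seq(2, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE])
}

# 2x block-max downsampling (keeps thin structures when shrinking masks).
downsample2_max <- function(m) {
  h <- nrow(m) %/% 2L; w <- ncol(m) %/% 2L
  m <- m[seq_len(2L * h), seq_len(2L * w), drop = FALSE]
  pmax(m[seq(1, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE],
       m[seq(2, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE],
       m[seq(1, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE],
       m[seq(2, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE])
}

downsample2_array <- function(a, fun = downsample2_mean) {
  out <- vapply(seq_len(dim(a)[3]), function(c) fun(a[, , c]),
                matrix(0, nrow(a) %/% 2L, ncol(a) %/% 2L))
  array(out, c(nrow(a) %/% 2L, ncol(a) %/% 2L, dim(a)[3]))
}

# Reflection-pad a matrix/array on the bottom/right to reach (h, w).
pad_reflect <- function(x, h, w) {
  d <- dim(x)
  ih <- d[1]; iw <- d[2]
  ridx <- c(seq_len(ih), rev(seq_len(ih)))[seq_len(h)]
  cidx <- c(seq_len(iw), rev(seq_len(iw)))[seq_len(w)]
  if (length(d) == 2) x[ridx, cidx, drop = FALSE] else x[ridx, cidx, , drop = FALSE]
}
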