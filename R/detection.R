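# Point-based nuclei detection primitives: repel-coded proximity targets,
# greedy non-maximum suppression, and one-to-one matching of detected against
# annotated centres.

#' Repel-coding parameters
#'
#' The repel code is a proximity map that peaks (value 1) at nucleus centres,
#' decays to 0 at distance `r`, and is suppressed in the corridor between
#' adjacent nuclei so that near neighbours remain separable peaks:
#' `R(p) = max(0, 1 - d1/r)^alpha * (1 - beta * d1 / max(d2, eps))`, with
#' `d1 <= d2` the distances to the two nearest centres.
#'
#' @param r Support radius in px (> 0).
#' @param alpha Peak sharpness (>= 1).
#' @param beta Valley weight in `[0, 1]`.
#' @return A `repel_params` list.
#' @export
repel_params <- function(r = 10, alpha = 2, beta = 0.8) {
  assert_that(r > 0, "r must be > 0", class = "pdl1tps_param_error")
  assert_that(alpha >= 1, "alpha must be >= 1", class = "pdl1tps_param_error")
  assert_that(beta >= 0 && beta <= 1, "beta must be in [0, 1]",
              class = "pdl1tps_param_error")
  structure(list(r = r, alpha = alpha, beta = beta), class = "repel_params")
}

#' Encode nucleus centres as a repel proximity raster
#'
#' @param centers Matrix or data frame with columns `x`, `y` (0-based pixel
#'   coordinates) or a 2-column matrix.
#' @param shape `c(height, width)` of the output raster.
#' @param params [repel_params()].
#' @return Matrix in `[0, 1]` of size `shape`.
#' @export
repel_encode <- function(centers, shape, params = repel_params()) {
  cm <- centers_matrix(centers)
  if (nrow(cm)) {
    assert_that(all(cm[, 1] >= 0 & cm[, 1] < shape[2] &
                      cm[, 2] >= 0 & cm[, 2] < shape[1]),
                "centers must lie within shape")
  }
  repel_map(cm, as.integer(shape[1]), as.integer(shape[2]),
            params$r, params$alpha, params$beta)
}

centers_matrix <- function(centers) {
  if (is.null(centers) || (is.data.frame(centers) && nrow(centers) == 0))
    return(matrix(numeric(0), 0, 2))
  if (is.data.frame(centers)) return(cbind(centers$x, centers$y))
  if (is.matrix(centers) && ncol(centers) >= 2) {
    if (!is.null(colnames(centers)) && all(c("x", "y") %in% colnames(centers)))
      return(cbind(centers[, "x"], centers[, "y"]))
    return(centers[, 1:2, drop = FALSE])
  }
  if (length(centers) == 0) return(matrix(numeric(0), 0, 2))
  abort("centers must be a matrix or data frame with x, y columns")
}

#' Non-maximum-suppression parameters
#'
#' @param min_distance Minimum mutual distance between returned peaks in px
#'   (>= 1); points at exactly `min_distance` are both kept.
#' @param score_threshold Minimum peak score in `[0, 1]`.
#' @return An `nms_params` list.
#' @export
nms_params <- function(min_distance = 5, score_threshold = 0.3) {
  assert_that(min_distance >= 1, "min_distance must be >= 1",
              class = "pdl1tps_param_error")
  assert_that(score_threshold >= 0 && score_threshold <= 1,
              "score_threshold must be in [0, 1]", class = "pdl1tps_param_error")
  structure(list(min_distance = min_distance, score_threshold = score_threshold),
            class = "nms_params")
}

#' Extract peak points from a score map by greedy non-maximum suppression
#'
#' Candidates are all pixels scoring at least `score_threshold`, processed in
#' decreasing score order (ties broken row-major); a candidate is kept iff it
#' is at least `min_distance` away from every already-kept point. Confidence
#' is the peak score.
#'
#' @param score_map Numeric matrix of scores in `[0, 1]`.
#' @param params [nms_params()].
#' @return Tibble with columns `x`, `y` (0-based), `confidence`.
#' @export
nms_points <- function(score_map, params = nms_params()) {
  assert_that(is.matrix(score_map), "score_map must be a matrix")
  out <- nms_greedy(score_map, params$min_distance, params$score_threshold)
  tibble::as_tibble(out)
}

#' Match detected points against annotated centres one-to-one
#'
#' Builds the bipartite graph of (prediction, truth) pairs at Euclidean
#' distance strictly below `max_dist` and takes a maximum-cardinality
#' one-to-one matching. TP = matched pairs, FP = unmatched predictions,
#' FN = unmatched truths.
#'
#' @param pred,truth Data frames with `x`, `y` columns (0-based coordinates).
#' @param max_dist Matching radius in px; pairs at distance >= `max_dist`
#'   cannot match (default 10).
#' @return A `detection_match` list: counts `tp`, `fp`, `fn`; `pairs` tibble
#'   (`pred_idx`, `truth_idx`, `dist`); `precision`, `recall`, `f1`.
#' @export
match_detections <- function(pred, truth, max_dist = 10) {
  assert_that(max_dist > 0, "max_dist must be > 0", class = "pdl1tps_param_error")
  pm <- centers_matrix(pred)
  tm <- centers_matrix(truth)
  np <- nrow(pm); nt <- nrow(tm)
  pairs <- tibble::tibble(pred_idx = integer(0), truth_idx = integer(0),
                          dist = numeric(0))
  if (np > 0 && nt > 0) {
    d <- sqrt(outer(pm[, 1], tm[, 1], "-")^2 + outer(pm[, 2], tm[, 2], "-")^2)
    edges <- which(d < max_dist, arr.ind = TRUE)
    if (nrow(edges) > 0) {
      g <- igraph::make_bipartite_graph(
        types = c(rep(FALSE, np), rep(TRUE, nt)),
        edges = as.vector(t(cbind(edges[, 1], np + edges[, 2]))))
      mm <- igraph::max_bipartite_match(g)$matching
      matched_pred <- which(!is.na(mm[seq_len(np)]))
      if (length(matched_pred)) {
        truth_idx <- as.integer(mm[matched_pred]) - np
        pairs <- tibble::tibble(
          pred_idx = matched_pred, truth_idx = truth_idx,
          dist = d[cbind(matched_pred, truth_idx)])
      }
    }
  }
  tp <- nrow(pairs)
  fp <- np - tp
  fn <- nt - tp
  precision <- if (np > 0) tp / np else NA_real_
  recall <- if (nt > 0) tp / nt else NA_real_
  f1 <- if (tp + 0.5 * (fp + fn) > 0) tp / (tp + 0.5 * (fp + fn)) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, pairs = pairs,
                 precision = precision, recall = recall, f1 = f1),
            class = "detection_match")
}

#' @export
print.detection_match <- function(x, ...) {
  cat(sprintf("<detection_match> TP %d, FP %d, FN %d (precision %.3f, recall %.3f, F1 %.3f)\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' @export
tidy.detection_match <- function(x, ...) x$pairs

#' @export
glance.detection_match <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = x$precision, recall = x$recall, f1 = x$f1)
}
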