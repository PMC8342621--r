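# Evaluation metrics: pixel metrics for segmentation, score-sweep metrics for
# point detection, and slide-level TPS agreement statistics.

#' Pixel-level segmentation metrics
#'
#' `overall_pixel_accuracy` (OPA) is `(TP + TN) / total`; `pixel_recall` is
#' `TP / (TP + FN)`. With an empty truth mask recall is defined as 1 (with a
#' warning), since no positive pixel was missed.
#'
#' @param pred_mask,true_mask Binary matrices of equal shape.
#' @return A fraction in `[0, 1]`.
#' @export
overall_pixel_accuracy <- function(pred_mask, true_mask) {
  assert_that(all(dim(pred_mask) == dim(true_mask)),
              "masks must have equal shape", class = "pdl1tps_format_error")
  mean((pred_mask > 0) == (true_mask > 0))
}

#' @rdname overall_pixel_accuracy
#' @export
pixel_recall <- function(pred_mask, true_mask) {
  assert_that(all(dim(pred_mask) == dim(true_mask)),
              "masks must have equal shape", class = "pdl1tps_format_error")
  npos <- sum(true_mask > 0)
  if (npos == 0) {
    warn("empty truth mask; recall defined as 1")
    return(1)
  }
  sum((pred_mask > 0) & (true_mask > 0)) / npos
}

#' Score-sweep precision/recall curve for point detection
#'
#' Sweeps the confidence threshold over the unique prediction confidences
#' (plus 0), re-matching predictions one-to-one against truth at each
#' threshold ([match_detections()], strict `< max_dist`). Reports the curve,
#' the F1 at `score_threshold`, and the area under the monotone-staircased
#' precision-recall curve (trapezoid over recall). Point detection has no true
#' negatives, so this score-sweep AUC is what the package reports as "AUC".
#'
#' @param pred Tibble with `x`, `y`, `confidence` in `[0, 1]`.
#' @param truth Tibble with `x`, `y`.
#' @param max_dist Matching radius in px (default 10, strict).
#' @param score_threshold Operating threshold for the reported F1.
#' @param max_thresholds Upper bound on swept thresholds; when the
#'   predictions carry more unique confidences than this, an evenly spaced
#'   quantile grid of this size is swept instead (default 64).
#' @return A `detection_pr` object: `curve` tibble (threshold, tp, fp, fn,
#'   precision, recall, f1), `f1`, `auc`.
#' @export
detection_pr_curve <- function(pred, truth, max_dist = 10,
                               score_threshold = 0.3, max_thresholds = 64) {
  pred <- tibble::as_tibble(pred)
  truth <- tibble::as_tibble(truth)
  if (nrow(pred) > 0) {
    assert_that(all(pred$confidence >= 0 & pred$confidence <= 1),
                "confidences must lie in [0, 1]")
  }
  if (nrow(pred) == 0 && nrow(truth) == 0) {
    warn("empty truth and empty predictions; F1 defined as 1")
    curve <- tibble::tibble(threshold = 0, tp = 0L, fp = 0L, fn = 0L,
                            precision = 1, recall = 1, f1 = 1)
    return(structure(list(curve = curve, f1 = 1, auc = 1,
                          auc_label = "detection score-sweep AUC"),
                     class = "detection_pr"))
  }
  thresholds <- sort(unique(c(0, pred$confidence)))
  if (length(thresholds) > max_thresholds) {
    thresholds <- sort(unique(c(0, quantile(pred$confidence,
                                            seq(0, 1, length.out = max_thresholds),
                                            names = FALSE))))
  }
  rows <- lapply(thresholds, function(th) {
    keep <- pred[pred$confidence >= th, , drop = FALSE]
    m <- match_detections(keep, truth, max_dist)
    tibble::tibble(threshold = th, tp = m$tp, fp = m$fp, fn = m$fn,
                   precision = if (nrow(keep)) m$precision else 1,
                   recall = m$recall %||% NA_real_, f1 = m$f1)
  })
  curve <- dplyr::bind_rows(rows)
  # F1 at the operating threshold
  m_op <- match_detections(pred[pred$confidence >= score_threshold, , drop = FALSE],
                           truth, max_dist)
  # staircase the precision envelope, then integrate over recall
  ord <- order(curve$recall, -curve$precision)
  rec <- c(0, curve$recall[ord])
  prec <- curve$precision[ord]
  prec_env <- rev(cummax(rev(prec)))
  prec_env <- c(prec_env[1], prec_env)
  auc <- sum(diff(rec) * (head(prec_env, -1) + prec_env[-1]) / 2)
  structure(list(curve = curve, f1 = m_op$f1, auc = auc,
                 auc_label = "detection score-sweep AUC"),
            class = "detection_pr")
}

#' @export
print.detection_pr <- function(x, ...) {
  cat(sprintf("<detection_pr> F1 %.3f, %s %.3f (%d thresholds)\n",
              x$f1, x$auc_label, x$auc, nrow(x$curve)))
  invisible(x)
}

#' @export
tidy.detection_pr <- function(x, ...) x$curve

#' @export
glance.detection_pr <- function(x, ...) {
  tibble::tibble(f1 = x$f1, auc = x$auc)
}

#' Slide-level TPS agreement report
#'
#' Computes the agreement statistics between predicted and reference TPS
#' values: MAE with a percentile-bootstrap 95% CI over cases (seeded,
#' `n_boot` resamples), Pearson correlation with its two-sided t-test
#' p-value, 3-class accuracy, and the 3x3 confusion matrix
#' (rows = truth, columns = predicted).
#'
#' @param pred_tps,true_tps Numeric vectors in `[0, 100]`, equal length.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level CI level (default 0.95).
#' @return An `agreement_report` object.
#' @export
agreement_report <- function(pred_tps, true_tps, n_boot = 2000, seed = 1L,
                             conf_level = 0.95) {
  assert_that(length(pred_tps) == length(true_tps),
              "pred and true TPS lists must have equal length")
  assert_that(all(pred_tps >= 0 & pred_tps <= 100) &&
                all(true_tps >= 0 & true_tps <= 100),
              "TPS values must lie in [0, 100]")
  n <- length(pred_tps)
  assert_that(n >= 3, "need at least 3 cases for the correlation test")
  err <- abs(pred_tps - true_tps)
  mae <- mean(err)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) mean(err[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- 1 - conf_level
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  ct <- if (stats::sd(pred_tps) > 0 && stats::sd(true_tps) > 0)
    cor.test(pred_tps, true_tps) else list(estimate = NA_real_, p.value = NA_real_)
  lv_true <- expression_level(true_tps)
  lv_pred <- expression_level(pred_tps)
  confusion <- table(truth = lv_true, predicted = lv_pred)
  acc3 <- sum(diag(confusion)) / n
  cases <- tibble::tibble(case = seq_len(n), true_tps = true_tps,
                          pred_tps = pred_tps,
                          true_level = lv_true, pred_level = lv_pred)
  structure(list(mae = mae, mae_ci = ci, pcc = unname(ct$estimate),
                 pcc_p = ct$p.value, acc3 = acc3,
                 confusion = unclass(confusion), n = n, cases = cases),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d: MAE %.2f (95%% CI %.2f-%.2f), PCC %.4f (p=%.3g), 3-class ACC %.1f%%\n",
              x$n, x$mae, x$mae_ci[1], x$mae_ci[2], x$pcc, x$pcc_p, 100 * x$acc3))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) x$cases

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n = x$n, mae = x$mae, mae_ci_lower = x$mae_ci[1],
                 mae_ci_upper = x$mae_ci[2], pcc = x$pcc, pcc_p = x$pcc_p,
                 acc3 = x$acc3)
}

#' Per-expression-level MAE
#'
#' MAE restricted to cases grouped by their TRUE expression level; empty
#' levels are absent from the result. Optionally drops negative-expression
#' cases first (`positive_only`).
#'
#' @param pred_tps,true_tps Numeric vectors in `[0, 100]`.
#' @param positive_only If `TRUE`, exclude cases whose true level is negative.
#' @return Tibble with `level`, `n`, `mae`.
#' @export
subgroup_mae <- function(pred_tps, true_tps, positive_only = FALSE) {
  assert_that(length(pred_tps) == length(true_tps),
              "pred and true TPS lists must have equal length")
  lv <- expression_level(true_tps)
  keep <- if (positive_only) lv != "negative" else rep(TRUE, length(lv))
  tibble::tibble(level = lv[keep], err = abs(pred_tps - true_tps)[keep]) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n = dplyr::n(), mae = mean(.data$err), .groups = "drop")
}
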