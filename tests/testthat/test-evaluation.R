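# Metric cross-checks against hand-computed and closed-form values.

test_that("OPA and recall match hand counts", {
  a <- matrix(1, 4, 4)
  expect_equal(overall_pixel_accuracy(a, a), 1)
  expect_equal(pixel_recall(a, a), 1)
  expect_equal(overall_pixel_accuracy(1 - a, a), 0)

  # 4x4 hand case: TP=6, TN=5, FP=2, FN=3
  truth <- matrix(c(1,1,1, 1,1,1, 1,1,1, 0,0,0, 0,0,0, 0), 4, 4)
  pred <- truth
  pred[c(1, 2, 3)] <- 0        # 3 FN
  pred[c(11, 12)] <- 1         # 2 FP
  expect_equal(sum(pred & truth), 6)
  expect_equal(overall_pixel_accuracy(pred, truth), 11 / 16)
  expect_equal(pixel_recall(pred, truth), 6 / 9)
  expect_warning(r <- pixel_recall(pred, matrix(0, 4, 4)), "recall")
  expect_equal(r, 1)
  expect_error(overall_pixel_accuracy(matrix(0, 2, 2), truth),
               class = "pdl1tps_format_error")
})

test_that("the PR sweep reproduces hand-computed precision/recall and AUC limits", {
  truth <- tibble::tibble(x = c(10, 30, 50), y = c(10, 30, 50))
  perfect <- tibble::tibble(x = truth$x, y = truth$y, confidence = 1)
  pr <- detection_pr_curve(perfect, truth)
  expect_equal(pr$f1, 1)
  expect_equal(pr$auc, 1)

  far <- tibble::tibble(x = truth$x + 50, y = truth$y, confidence = 1)
  expect_equal(detection_pr_curve(far, truth, score_threshold = 0.5)$f1, 0)

  # 5-point constructed example: 3 truths; detections at confidences
  # 0.9 (hit), 0.8 (miss), 0.7 (hit), 0.6 (miss), 0.5 (hit)
  pred <- tibble::tibble(
    x = c(10, 100, 30, 120, 50), y = c(10, 100, 30, 120, 50),
    confidence = c(0.9, 0.8, 0.7, 0.6, 0.5))
  pr2 <- detection_pr_curve(pred, truth, score_threshold = 0.65)
  cv <- pr2$curve
  # hand-computed: at th 0.9 -> P 1/1, R 1/3; th 0.8 -> 1/2, 1/3;
  # th 0.7 -> 2/3, 2/3; th 0.6 -> 2/4, 2/3; th <= 0.5 -> 3/5, 1
  expect_equal(cv$precision[cv$threshold == 0.9], 1)
  expect_equal(cv$recall[cv$threshold == 0.9], 1 / 3)
  expect_equal(cv$precision[cv$threshold == 0.8], 1 / 2)
  expect_equal(cv$precision[cv$threshold == 0.7], 2 / 3)
  expect_equal(cv$recall[cv$threshold == 0.7], 2 / 3)
  expect_equal(cv$precision[cv$threshold == 0.5], 3 / 5)
  expect_equal(cv$recall[cv$threshold == 0.5], 1)
  # F1 at the operating threshold equals the direct single-threshold value
  direct <- match_detections(pred[pred$confidence >= 0.65, ], truth, 10)
  expect_equal(pr2$f1, direct$f1)
})

test_that("agreement report matches closed-form MAE/PCC and bootstrap behaves", {
  x <- c(5, 20, 40, 60, 80, 95)
  r0 <- agreement_report(x, x, n_boot = 200, seed = 1)
  expect_equal(r0$mae, 0)
  expect_equal(r0$pcc, 1, tolerance = 1e-12)
  expect_equal(r0$acc3, 1)

  r5 <- agreement_report(pmin(x + 5, 100), pmin(x + 0, 100), n_boot = 200, seed = 1)
  expect_equal(r5$mae, 5)
  expect_equal(r5$pcc, 1, tolerance = 1e-9)

  # 6-case hand example against direct formula evaluation
  pred <- c(2, 10, 35, 55, 75, 90)
  true <- c(0, 15, 30, 50, 80, 95)
  rep6 <- agreement_report(pred, true, n_boot = 2000, seed = 7)
  expect_equal(rep6$mae, mean(abs(pred - true)), tolerance = 1e-12)
  expect_equal(rep6$pcc, cor(pred, true), tolerance = 1e-12)
  expect_equal(rep6$pcc_p, cor.test(pred, true)$p.value, tolerance = 1e-12)
  expect_true(rep6$mae_ci[1] <= rep6$mae && rep6$mae <= rep6$mae_ci[2])
  expect_equal(sum(rep6$confusion), 6)
  expect_equal(unname(rowSums(rep6$confusion)),
               unname(as.vector(table(expression_level(true)))))

  expect_error(agreement_report(1:4, 1:5))
  expect_error(agreement_report(c(1, 2), c(1, 2)))
})

test_that("the bootstrap CI narrows as n grows", {
  set.seed(11)
  mk <- function(n) {
    true <- runif(n, 0, 100)
    pred <- pmin(pmax(true + rnorm(n, 0, 8), 0), 100)
    agreement_report(pred, true, n_boot = 500, seed = 3)
  }
  r10 <- mk(10); r100 <- mk(100)
  expect_lt(diff(r100$mae_ci), diff(r10$mae_ci))
})

test_that("subgroup MAE recovers planted per-level errors and filters negatives", {
  true <- c(0, 0.5, 0.9, 10, 20, 30, 60, 75, 90)
  pred <- pmin(100, true + rep(c(2, 5, 8), each = 3) * rep(c(1, 1, 1), 3))
  sg <- subgroup_mae(pred, true)
  expect_equal(sg$mae[sg$level == "negative"], 2)
  expect_equal(sg$mae[sg$level == "low"], 5)
  expect_equal(sg$mae[sg$level == "high"], 8)
  expect_equal(sg$n, c(3L, 3L, 3L))

  pos <- subgroup_mae(pred, true, positive_only = TRUE)
  expect_false("negative" %in% as.character(pos$level))
  expect_equal(mean(abs(pred - true)[true >= 1]), mean(rep(c(5, 8), each = 3)))

  # all cases in one level: subgroup MAE equals overall MAE
  one <- subgroup_mae(c(60, 70, 80), c(55, 77, 85))
  expect_equal(nrow(one), 1L)
  expect_equal(one$mae, mean(abs(c(60, 70, 80) - c(55, 77, 85))))
})

test_that("acc3 is invariant under simultaneous permutation of cases", {
  set.seed(21)
  true <- runif(12, 0, 100)
  pred <- pmin(pmax(true + rnorm(12, 0, 15), 0), 100)
  r1 <- agreement_report(pred, true, n_boot = 100, seed = 1)
  perm <- sample(12)
  r2 <- agreement_report(pred[perm], true[perm], n_boot = 100, seed = 1)
  expect_equal(r1$acc3, r2$acc3)
  expect_equal(r1$confusion, r2$confusion)
})
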