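# TPS arithmetic, expression-level brackets, nucleus labelling against masks,
# and cell-weighted slide aggregation.

test_that("compute_tps follows the defining ratio and rejects empty slides", {
  expect_equal(compute_tps(0, 500), 0)
  expect_equal(compute_tps(500, 500), 100)
  expect_equal(compute_tps(137, 411), 33.33, tolerance = 0.01)
  expect_error(compute_tps(0, 0), class = "pdl1tps_no_tumor_error")
  expect_error(compute_tps(5, 3))
})

test_that("expression levels use the <1 / 1-49 / >=50 brackets exactly", {
  expect_equal(as.character(expression_level(0.9)), "negative")
  expect_equal(as.character(expression_level(1.0)), "low")
  expect_equal(as.character(expression_level(49.99)), "low")
  expect_equal(as.character(expression_level(50.0)), "high")
  expect_equal(as.character(expression_level(c(0, 100))), c("negative", "high"))
  expect_error(expression_level(101))
})

test_that("classify_nuclei uses the tumor mask and the scoring disc", {
  tumor <- as_mask(matrix(0, 16, 16), 20)
  tumor[5:10, 5:10] <- 1
  pos <- as_mask(matrix(0, 32, 32), 40)
  pos[12, 12] <- 1   # positive pixel at 40x (11,11) 0-based
  pts <- tibble::tibble(x = c(12, 16, 40), y = c(12, 18, 40))
  out <- classify_nuclei(pts, tumor, pos, rho = 8)
  # point 1: tumor (20x cell (6,6)), positive pixel 1.4 px away
  expect_true(out$is_tumor[1] && out$is_positive[1])
  # point 2: tumor (20x cell (8,9)) but nearest positive pixel 8.6 px away
  expect_true(out$is_tumor[2])
  expect_false(out$is_positive[2])
  # point 3: outside the tumor mask entirely
  expect_false(out$is_tumor[3])
  expect_false(out$is_positive[3])

  res <- score_points(out)
  expect_equal(res$n_tt, 2L)
  expect_error(classify_nuclei(pts, matrix(0, 16, 16), pos),
               class = "pdl1tps_contract_error")
})

test_that("oracle masks reproduce planted labels and TPS exactly on a synthetic slide", {
  sl <- fixture_slide(201, planted_tps = 60)
  lab <- classify_nuclei(sl$nuclei[, c("x", "y")], sl$tumor_mask20,
                         sl$membrane_mask40, rho = 8)
  agree <- mean(lab$is_tumor == sl$nuclei$is_tumor &
                  lab$is_positive == sl$nuclei$is_positive)
  expect_gte(agree, 0.99)
  res <- score_points(lab)
  expect_equal(res$tps_percent, sl$realized_tps, tolerance = 1e-9)
})

test_that("slide aggregation is cell-weighted, order-invariant and consistent", {
  t1 <- tibble::tibble(n_pt = c(10, 90), n_tt = c(100, 100))
  expect_equal(score_slide(t1)$tps_percent, 50)
  t2 <- tibble::tibble(n_pt = c(10, 90), n_tt = c(100, 900))
  expect_equal(score_slide(t2)$tps_percent, 10)
  expect_equal(score_slide(t2[2:1, ])$tps_percent, 10)
  one <- score_slide(tibble::tibble(n_pt = 137, n_tt = 411))
  expect_equal(one$tps_percent, compute_tps(137, 411))
  expect_error(score_slide(tibble::tibble(n_pt = 5, n_tt = 3)))
  expect_error(score_slide(tibble::tibble(n_pt = 0, n_tt = 0)),
               class = "pdl1tps_no_tumor_error")
})

test_that("flipping a tumor cell to positive never decreases the TPS", {
  set.seed(31)
  pts <- tibble::tibble(x = runif(60, 0, 100), y = runif(60, 0, 100),
                        is_tumor = runif(60) < 0.7,
                        is_positive = FALSE)
  pts$is_positive <- pts$is_tumor & (runif(60) < 0.4)
  base <- score_points(pts)$tps_percent
  for (i in which(pts$is_tumor & !pts$is_positive)[1:5]) {
    flipped <- pts
    flipped$is_positive[i] <- TRUE
    expect_gte(score_points(flipped)$tps_percent, base)
  }
})

test_that("tidy and glance expose counts and breakdown", {
  res <- score_slide(tibble::tibble(n_pt = c(1, 2), n_tt = c(10, 20)))
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n_pt, 3)
  expect_equal(g$tps_percent, 10)
  expect_equal(g$expression_level, "low")
})
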