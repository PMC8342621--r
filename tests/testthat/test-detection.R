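# Repel coding, greedy NMS, and one-to-one detection matching, each checked
# against an independent oracle.

test_that("repel code peaks at centres, vanishes beyond the radius, and stays in [0,1]", {
  p <- repel_params(r = 10, alpha = 2, beta = 0.8)
  expect_equal(repel_encode(NULL, c(32, 32), p), matrix(0, 32, 32))

  one <- repel_encode(data.frame(x = 16, y = 16), c(33, 33), p)
  expect_equal(one[17, 17], 1)
  expect_equal(one[17, 27], 0)         # distance exactly r
  expect_equal(one[17, 30], 0)         # beyond r
  expect_true(all(one >= 0 & one <= 1))
  # argmax in the r/2-neighbourhood of the centre is the centre itself
  nb <- one[17 + (-5:5), 17 + (-5:5)]
  expect_equal(which.max(nb), 61L)     # centre of the 11x11 window
})

test_that("repel code forms a valley between near neighbours (formula oracle)", {
  p <- repel_params(r = 10, alpha = 2, beta = 0.8)
  # two centres 0.5 r apart; pixel x=23 sits in the corridor (d1=2, d2=3)
  m <- repel_encode(data.frame(x = c(20, 25), y = c(20, 20)), c(41, 61), p)
  expected_corridor <- (1 - 2 / p$r)^p$alpha * (1 - p$beta * 2 / 3)
  expect_equal(m[21, 24], expected_corridor, tolerance = 1e-9)
  # an isolated nucleus at the same d1 = 2 scores much higher (no valley)
  iso <- repel_encode(data.frame(x = 20, y = 20), c(41, 61), p)
  expect_equal(iso[21, 23], (1 - 2 / p$r)^p$alpha, tolerance = 1e-9)
  expect_lt(m[21, 24], iso[21, 23] - 0.2)
  # whole-raster brute force at modest size
  ctr <- data.frame(x = c(7, 12, 30), y = c(9, 9, 25))
  enc <- repel_encode(ctr, c(40, 40), p)
  brute <- matrix(0, 40, 40)
  for (yy in 0:39) for (xx in 0:39) {
    d <- sort(sqrt((ctr$x - xx)^2 + (ctr$y - yy)^2))
    brute[yy + 1, xx + 1] <-
      max(0, 1 - d[1] / p$r)^p$alpha * (1 - p$beta * d[1] / max(d[2], 1e-9))
  }
  expect_equal(enc, brute, tolerance = 1e-9)
})

test_that("NMS handles trivial maps and respects the distance constraint", {
  expect_equal(nrow(nms_points(matrix(0, 32, 32))), 0L)
  m <- matrix(0, 40, 40)
  m[10, 10] <- 1; m[10, 25] <- 1        # 15 px apart, min_distance 5
  out <- nms_points(m, nms_params(min_distance = 5, score_threshold = 0.3))
  expect_equal(nrow(out), 2L)
  expect_setequal(out$x, c(9, 24))
  # sub-threshold noise leaves the result unchanged
  set.seed(4)
  noise <- matrix(runif(1600, 0, 0.29), 40, 40)
  out2 <- nms_points(pmax(m, noise), nms_params(min_distance = 5, score_threshold = 0.3))
  expect_equal(out2, out)
})

test_that("NMS equals the brute-force greedy oracle on 100 random maps", {
  set.seed(100)
  p <- nms_params(min_distance = 4, score_threshold = 0.5)
  for (i in 1:100) {
    score <- matrix(0, 64, 64)
    n_pk <- sample(3:20, 1)
    idx <- sample(64 * 64, n_pk)
    score[idx] <- runif(n_pk, 0.3, 1)
    got <- nms_points(score, p)
    want <- nms_oracle(score, p$min_distance, p$score_threshold)
    expect_equal(as.data.frame(got), want)
  }
})

test_that("matching is one-to-one with strict sub-10px pairing", {
  pts <- tibble::tibble(x = c(5, 30, 60), y = c(5, 30, 60))
  m <- match_detections(pts, pts, 10)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  expect_equal(m$f1, 1)

  # one prediction within 10 px of two truths: only one can match
  m2 <- match_detections(tibble::tibble(x = 10, y = 10),
                         tibble::tibble(x = c(7, 13), y = c(10, 10)), 10)
  expect_equal(c(m2$tp, m2$fn), c(1L, 1L))

  # distance exactly max_dist does not match (strict inequality)
  m3 <- match_detections(tibble::tibble(x = 0, y = 0),
                         tibble::tibble(x = 10, y = 0), 10)
  expect_equal(m3$tp, 0L)
})

test_that("matching count equals independent oracles on random instances", {
  set.seed(200)
  for (i in 1:100) {
    pred <- random_points(sample(0:20, 1))
    truth <- random_points(sample(0:20, 1))
    m <- match_detections(pred, truth, 10)
    expect_equal(m$tp, matching_oracle(pred, truth, 10))
    expect_equal(m$fp, nrow(pred) - m$tp)
    expect_equal(m$fn, nrow(truth) - m$tp)
    if (!nrow(m$pairs) == 0) expect_true(all(m$pairs$dist < 10))
  }
  # exhaustive assignment search on small instances
  set.seed(201)
  for (i in 1:20) {
    pred <- random_points(sample(0:6, 1), lim = 25)
    truth <- random_points(sample(0:6, 1), lim = 25)
    expect_equal(match_detections(pred, truth, 10)$tp,
                 matching_exhaustive(pred, truth, 10))
  }
})
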