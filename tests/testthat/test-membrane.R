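# Positive-membrane detection: DoG band-pass, LAMT, luminance weighting,
# morphological cleanup, and the composed detector on generated tiles.

test_that("DoG rejects constant input and matches the kernel difference on an impulse", {
  const <- matrix(5, 64, 64)
  expect_lt(max(abs(dog_filter(const, 1, 2))), 1e-9)

  img <- matrix(0, 65, 65)
  img[33, 33] <- 1
  resp <- dog_filter(img, 1, 2)
  kn <- gaussian_kernel2d(1)   # radius 4
  kw <- gaussian_kernel2d(2)   # radius 8
  expected <- matrix(0, 65, 65)
  expected[33 + (-4:4), 33 + (-4:4)] <- expected[33 + (-4:4), 33 + (-4:4)] + kn
  expected[33 + (-8:8), 33 + (-8:8)] <- expected[33 + (-8:8), 33 + (-8:8)] - kw
  expect_lt(max(abs(resp - expected)), 1e-6)
  expect_error(dog_filter(const, -1, 2), class = "pdl1tps_param_error")
  expect_error(dog_filter(const, 2, 1), class = "pdl1tps_param_error")
})

test_that("DoG is a band-pass: thin ridge responds more than wide plateau", {
  img <- matrix(0, 40, 120)
  img[, 20 + (0:2)] <- 1     # 3 px ridge
  img[, 60 + (0:29)] <- 1    # 30 px plateau
  resp <- dog_filter(img, 1, 2)
  expect_gt(max(resp[20, 20:23]), max(resp[20, 65:85]) + 0.05)
})

test_that("LAMT yields no candidates on flat planes and confines them to the stained half", {
  p <- membrane_params()
  expect_equal(sum(lamt_classify(matrix(0, 128, 128), p)), 0)
  u <- lamt_classify(matrix(0.5, 128, 128), p)
  expect_true(all(u == 0) || all(u == 1))

  set.seed(1)
  dab <- matrix(0, 128, 128)
  # stained half: scattered high-OD 'rings' over faint background
  stained <- matrix(runif(128 * 64) < 0.15, 128, 64) * runif(128 * 64, 0.5, 0.9)
  dab[, 65:128] <- stained
  cand <- lamt_classify(dab, p)
  expect_gt(sum(cand), 0)
  expect_gte(sum(cand[, 65:128]) / sum(cand), 0.99)
})

test_that("LAMT falls back to a global block with a warning when the block exceeds the image", {
  p <- membrane_params(lamt_block = 512)
  expect_warning(lamt_classify(matrix(runif(32 * 32), 32, 32), p),
                 "global block")
})

test_that("luminance weighting removes bright candidates and is monotone in the threshold", {
  cand <- matrix(1, 2, 2)
  rgb <- array(0, c(2, 2, 3))
  rgb[1, 1, ] <- 255          # pure white -> removed
  rgb[1, 2, ] <- 5            # near black -> kept
  rgb[2, , ] <- 128
  kept <- luminance_weighted_threshold(cand, rgb, 0.3)
  expect_equal(kept[1, 1], 0)
  expect_equal(kept[1, 2], 1)

  sl <- fixture_slide(201, planted_tps = 60)
  tl <- fixture_tumor_tile(sl)
  rgb_tile <- tl$image * 255
  conc <- deconvolve(rgb_to_od(rgb_tile))
  cand2 <- lamt_classify(conc[, , 2], membrane_params())
  sizes <- vapply(c(0, 0.2, 0.4, 0.6, 0.95), function(th)
    sum(luminance_weighted_threshold(cand2, rgb_tile, th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("morphological cleanup removes dots, seals broken rings, and is idempotent", {
  p <- membrane_params(open_radius = 1, close_radius = 2,
                       max_hole_area = 400, min_object_area = 0)
  m <- matrix(0, 32, 32)
  m[16, 16] <- 1
  expect_equal(sum(postprocess_mask(m, p)), 0)

  # a 1-px-broken thick ring: closing seals it, the interior hole fills
  ring <- matrix(0, 48, 48)
  for (y in 1:48) for (x in 1:48) {
    r <- sqrt((x - 24)^2 + (y - 24)^2)
    if (r >= 8 && r <= 11) ring[y, x] <- 1
  }
  ring[24, 32:35] <- 0  # 1-px radial break
  out <- postprocess_mask(ring, p)
  lab <- EBImage::bwlabel(out)
  expect_equal(max(lab), 1)
  # simply connected: complement has a single (border) component
  expect_equal(max(EBImage::bwlabel(1 - out)), 1)
  expect_gt(sum(out[20:28, 20:28]), 60)  # interior filled

  p2 <- membrane_params()
  set.seed(9)
  noisy <- matrix(rbinom(64 * 64, 1, 0.2), 64, 64)
  once <- postprocess_mask(noisy, p2)
  expect_identical(postprocess_mask(once, p2), once)
})

test_that("the composed detector is specific, accurate and deterministic on synthetic tiles", {
  blank <- array(255, c(64, 64, 3))
  expect_equal(sum(detect_positive_membrane(blank)), 0)

  sl <- fixture_slide(201, planted_tps = 60)
  tl <- fixture_tumor_tile(sl)
  m1 <- detect_positive_membrane(tl$image * 255)
  m2 <- detect_positive_membrane(tl$image * 255)
  expect_identical(m1, m2)
  iou <- sum(m1 & tl$membrane) / sum(m1 | tl$membrane)
  expect_gte(iou, 0.6)

  # hematoxylin-only slide: positive area below 0.5%
  sl0 <- fixture_slide(202, planted_tps = 0)
  tl0 <- fixture_tumor_tile(sl0)
  m0 <- detect_positive_membrane(tl0$image * 255)
  expect_lt(mean(m0), 0.005)
})

test_that("detected positive area is monotone in planted DAB stain strength", {
  areas <- vapply(c(0.6, 1, 1.4), function(s) {
    sl <- generate_slide(synthetic_slide_spec(
      seed = 203, size = 512, planted_tps = 60, dab_od = s * c(0.55, 0.95)))
    tl <- fixture_tumor_tile(sl)
    sum(detect_positive_membrane(tl$image * 255))
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})
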