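# The synthetic H-DAB generator: determinism, planted truth consistency,
# stain fidelity, and dataset emission.

test_that("identical specs render bit-identical slides", {
  a <- generate_slide(synthetic_slide_spec(seed = 5, size = 256))
  b <- generate_slide(synthetic_slide_spec(seed = 5, size = 256))
  expect_identical(a$rgb40, b$rgb40)
  expect_identical(a$nuclei, b$nuclei)
  c <- generate_slide(synthetic_slide_spec(seed = 6, size = 256))
  expect_false(identical(a$rgb40, c$rgb40))
})

test_that("planted TPS 0 yields an empty membrane mask and realized TPS 0", {
  sl <- fixture_slide(202, planted_tps = 0)
  expect_equal(sum(sl$membrane_mask40), 0)
  expect_equal(sl$realized_tps, 0)
})

test_that("realized TPS tracks the planted rate and equals the label ratio exactly", {
  sl <- fixture_slide(204, planted_tps = 50)
  n_tumor <- sum(sl$nuclei$is_tumor)
  expect_gte(n_tumor, 400)
  expect_lt(abs(sl$realized_tps - 50), 5)
  expect_equal(sl$realized_tps,
               100 * sum(sl$nuclei$is_tumor & sl$nuclei$is_positive) / n_tumor)
})

test_that("masks, coordinates and hard-core spacing satisfy the generator contract", {
  sl <- fixture_slide(204, planted_tps = 50)
  n <- sl$spec$size
  expect_true(all(sl$tumor_mask40 %in% c(0, 1)))
  expect_true(all(sl$membrane_mask40 %in% c(0, 1)))
  expect_equal(dim(sl$tumor_mask20), dim(sl$tumor_mask40) / 2)
  expect_true(all(sl$nuclei$x >= 0 & sl$nuclei$x < n &
                    sl$nuclei$y >= 0 & sl$nuclei$y < n))
  tum <- sl$nuclei[sl$nuclei$is_tumor, ]
  d <- as.matrix(dist(cbind(tum$x, tum$y)))
  diag(d) <- Inf
  expect_gte(min(d), sl$spec$tumor_spacing)
  # tumor nuclei sit inside the viable mask, stromal outside the nests
  expect_true(all(sl$tumor_mask40[cbind(tum$y + 1, tum$x + 1)] == 1))
  str <- sl$nuclei[!sl$nuclei$is_tumor, ]
  expect_true(all(sl$tumor_mask40[cbind(str$y + 1, str$x + 1)] == 0))
})

test_that("every positive tumor cell has membrane staining inside its scoring disc", {
  sl <- fixture_slide(201, planted_tps = 60)
  pos <- sl$nuclei[sl$nuclei$is_tumor & sl$nuclei$is_positive, ]
  mem <- which(sl$membrane_mask40 > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(pos))) {
    dmin <- min(sqrt((mem[, 2] - 1 - pos$x[i])^2 + (mem[, 1] - 1 - pos$y[i])^2))
    expect_lte(dmin, 8)
  }
})

test_that("deconvolving a noise-free rendering recovers the planted DAB field", {
  sl <- generate_slide(synthetic_slide_spec(seed = 207, size = 512,
                                            planted_tps = 60, noise_sd = 0))
  conc <- deconvolve(rgb_to_od(sl$rgb40))
  expect_gt(cor(as.vector(conc[, , 2]), as.vector(sl$dab_conc40)), 0.99)
})

test_that("zero-density specs fail with the no-tumor contract", {
  expect_error(generate_slide(synthetic_slide_spec(seed = 1, size = 256,
                                                   tumor_fraction = 0.01,
                                                   tumor_spacing = 200)),
               class = "pdl1tps_error")
})

test_that("training-tile emission honours the negative:positive ratio", {
  tiles <- simulate_training_tiles(10, "det", seed = 31)
  expect_equal(nrow(tiles), 10L)
  expect_equal(sum(tiles$planted_tps == 0), 3L)
  expect_equal(sum(tiles$planted_tps > 0), 7L)
  seg <- simulate_training_tiles(4, "seg", seed = 32)
  for (i in seq_len(4)) {
    expect_equal(dim(seg$image[[i]]), c(512L, 512L, 3L))
    expect_equal(dim(seg$mask[[i]]), c(512L, 512L))
    expect_true(all(seg$mask[[i]] %in% c(0, 1)))
  }
})

test_that("emitted datasets are reproducible byte-for-byte", {
  d1 <- file.path(tempdir(), "emit1"); d2 <- file.path(tempdir(), "emit2")
  unlink(c(d1, d2), recursive = TRUE)
  base <- synthetic_slide_spec(size = 512)
  m1 <- emit_training_sets(d1, n_seg = 2, n_det = 4, seed = 9, base_spec = base)
  m2 <- emit_training_sets(d2, n_seg = 2, n_det = 4, seed = 9, base_spec = base)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  # images and masks pair up and parse
  img <- read_rgb_png(file.path(d1, "seg/images/seg_0001.png"))
  msk <- read_mask_png(file.path(d1, "seg/masks/seg_0001.png"))
  expect_equal(dim(img)[1:2], dim(msk))
  pts <- read_points_csv(list.files(file.path(d1, "det/centers"),
                                    full.names = TRUE)[1])
  expect_true(all(c("x", "y", "confidence", "is_tumor", "is_positive") %in% names(pts)))
})

test_that("difficulty knobs degrade pipeline inputs plausibly (noise raises DAB residual)", {
  base <- generate_slide(synthetic_slide_spec(seed = 208, size = 256,
                                              planted_tps = 50, noise_sd = 0))
  noisy <- generate_slide(synthetic_slide_spec(seed = 208, size = 256,
                                               planted_tps = 50, noise_sd = 8))
  r0 <- cor(as.vector(deconvolve(rgb_to_od(base$rgb40))[, , 2]),
            as.vector(base$dab_conc40))
  r8 <- cor(as.vector(deconvolve(rgb_to_od(noisy$rgb40))[, , 2]),
            as.vector(noisy$dab_conc40))
  expect_gt(r0, r8)
})
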