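# Architecture contracts of the two networks (shape, configuration
# validation, receptive field, determinism of splitting, small overfits).

tiny_seg_cfg <- function(...) {
  seg_model_config(width_multiplier = 1 / 8, blocks_per_stage = c(1, 1, 1, 1), ...)
}

test_that("segmentation forward maps HxWx3 to HxWx2 at full resolution", {
  m <- build_res50_unet(tiny_seg_cfg(), seed = 1)
  x <- array(runif(96 * 96 * 3), c(96, 96, 3))
  out <- pdl1tps:::seg_forward(m, x)
  expect_equal(dim(out$value), c(96, 96, 2))
  # per-pixel softmax normalisation via the prediction path
  probs <- predict_class_probs(m, array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3)))
  expect_equal(dim(probs), c(64, 64, 2))
  sums <- probs[, , 1] + probs[, , 2]
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("config contracts: ASPP rates, input size, decoder widths", {
  expect_error(seg_model_config(aspp_rates = c(2, 1, 4, 7)),
               class = "pdl1tps_config_error")
  expect_error(seg_model_config(input_size = 500),
               class = "pdl1tps_config_error")
  expect_error(seg_model_config(pretrained = TRUE),
               class = "pdl1tps_config_error")
  base <- build_res50_unet(tiny_seg_cfg(), seed = 1)
  halved <- build_res50_unet(tiny_seg_cfg(decoder_channels = c(8, 4, 4)), seed = 1)
  expect_false(count_params(base) == count_params(halved))
})

test_that("wider ASPP rates enlarge the analytic receptive field", {
  rf_wide <- receptive_field(build_res50_unet(tiny_seg_cfg(), seed = 1))
  rf_narrow <- receptive_field(build_res50_unet(
    tiny_seg_cfg(aspp_rates = c(1, 2, 3, 4)), seed = 1))
  expect_gt(rf_wide, rf_narrow)
  # the default 50-layer configuration is deeper still
  rf_full <- receptive_field(structure(list(config = seg_model_config()),
                                       class = "seg_model"))
  expect_gt(rf_full, rf_wide)
})

test_that("fold assignments are deterministic partitions", {
  f1 <- make_folds(20, 10, seed = 3)
  f2 <- make_folds(20, 10, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:10)
  expect_true(all(table(f1) == 2))
  expect_false(identical(f1, make_folds(20, 10, seed = 4)))
})

test_that("threshold extremes produce empty and full masks", {
  m <- build_res50_unet(tiny_seg_cfg(), seed = 2)
  tile <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  expect_equal(sum(predict_tumor_mask(m, tile, threshold = 1)$binary), 0)
  expect_equal(sum(predict_tumor_mask(m, tile, threshold = 0)$binary), 64 * 64)
  pr <- predict_tumor_mask(m, tile)$prob
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("mask inference is translation-consistent away from boundaries", {
  m <- build_res50_unet(tiny_seg_cfg(), seed = 5)
  set.seed(8)
  n <- 512
  big <- array(runif(n * n * 3), c(n, n, 3))
  p1 <- predict_tumor_mask(m, big)$prob
  shift <- 32
  p2 <- predict_tumor_mask(m, big[(shift + 1):n, , , drop = FALSE])$prob
  # padding influence reaches half the receptive field (~116 px here) inward;
  # beyond that, a 32-px shift leaves the computation identical
  band <- 160
  inner_rows <- (band + 1):(n - shift - band)
  inner_cols <- (band + 1):(n - band)
  expect_lt(max(abs(p1[inner_rows + shift, inner_cols] - p2[inner_rows, inner_cols])),
            1e-9)
})

test_that("micronet emits one output per resolution branch with valid ranges", {
  cfg <- det_model_config(base_channels = 4)
  m <- build_micronet(cfg, seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- pdl1tps:::det_forward(m, x)
  expect_equal(dim(out$main$value), c(64, 64, 1))
  expect_true(all(out$main$value >= 0 & out$main$value <= 1))
  expect_equal(length(out$aux) + 1L, length(cfg$resolution_branches))
  expect_equal(dim(out$aux$level3$value)[1:2], c(16, 16))
  expect_equal(dim(out$aux$level2$value)[1:2], c(32, 32))

  no_ds <- build_micronet(det_model_config(base_channels = 4,
                                           deep_supervision = FALSE), seed = 1)
  out2 <- pdl1tps:::det_forward(no_ds, x)
  expect_equal(length(out2$aux), 0L)

  expect_error(det_model_config(resolution_branches = c(2, 4)),
               class = "pdl1tps_config_error")
  expect_error(det_model_config(resolution_branches = c(1, 3)),
               class = "pdl1tps_config_error")
})

test_that("the detector can overfit four tiles to sub-1e-3 regression MSE", {
  det_tiles <- simulate_training_tiles(4, "det", seed = 56)
  rp <- repel_params()
  # peak-weighted warm-up escapes the constant-field attractor, then two
  # warm-started polishing phases progressively flatten the background
  d <- train_nuclei_detector(det_tiles, det_model_config(),
    train_config(epochs = 80, lr = 2e-3, batch = 4, seed = 10, crop = 96),
    calibrate = FALSE)
  d <- train_nuclei_detector(det_tiles, det_model_config(),
    train_config(epochs = 80, lr = 1e-3, batch = 4, seed = 11, crop = 96),
    w_pos = 1, calibrate = FALSE, init_model = d)
  d <- train_nuclei_detector(det_tiles, det_model_config(),
    train_config(epochs = 60, lr = 5e-4, batch = 4, seed = 12, crop = 96),
    w_pos = 0, calibrate = FALSE, init_model = d)
  mse <- mean(vapply(1:4, function(i) {
    sc <- predict_nuclei_scores(d, det_tiles$image[[i]])
    mean((sc - repel_encode(det_tiles$centers[[i]], dim(sc), rp))^2)
  }, numeric(1)))
  expect_lt(mse, 1e-3)
})

test_that("training is deterministic given the seed (segmentation smoke)", {
  samp <- lapply(1:2, function(i) {
    sl <- fixture_slide(210 + i, size = 256, planted_tps = 40)
    list(image = sl$rgb20 / 255, mask = unclass(sl$tumor_mask20)[, ])
  })
  tc <- train_config(epochs = 1, lr = 1e-3, batch = 2, seed = 7, crop = 64)
  cfg <- tiny_seg_cfg()
  m1 <- train_segmentation(samp, cfg, tc)
  m2 <- train_segmentation(samp, cfg, tc)
  expect_equal(m1$metrics, m2$metrics, tolerance = 1e-12)
  expect_error(train_segmentation(list(), cfg, tc))
})
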