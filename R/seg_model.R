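# Tumor-region segmentation: a U-Net-style encoder-decoder whose encoder is a
# bottleneck residual network with the striding of the last two stages
# replaced by dilated convolution (rates 2 and 4, output stride 8), an atrous
# spatial pyramid pooling (ASPP) block with rates [1, 2, 4, 7] between encoder
# and decoder, and skip connections from the stride-2/4 encoder stages.

#' Segmentation model configuration
#'
#' The default mirrors a 50-layer bottleneck residual encoder (stages of
#' 3/4/6/3 blocks, widths 256/512/1024/2048). `width_multiplier` and
#' `blocks_per_stage` scale the model down for CPU-scale experiments without
#' changing the architecture contract: output stride 8 via dilation in the
#' last two stages, ASPP between encoder and decoder, skip-connected decoder
#' back to full resolution.
#'
#' @param encoder Encoder identifier (currently `"resnet50"`).
#' @param dilate_rates_last_blocks Dilation rates replacing the striding of
#'   the last two encoder stages (default `c(2, 4)`).
#' @param aspp_rates Strictly increasing ASPP dilation rates
#'   (default `c(1, 2, 4, 7)`).
#' @param decoder_channels Widths of the three decoder stages (coarse to
#'   fine); default scales with `width_multiplier`.
#' @param num_classes Number of output classes (default 2).
#' @param input_size Nominal tile side, divisible by 32 (default 512).
#' @param pretrained Placeholder flag for a pretrained encoder; no pretrained
#'   weights ship with the package, so only `FALSE` is accepted.
#' @param width_multiplier Multiplies all channel widths (default 1).
#' @param blocks_per_stage Residual blocks per encoder stage (default
#'   `c(3, 4, 6, 3)`).
#' @return A `seg_model_config` object.
#' @export
seg_model_config <- function(encoder = "resnet50",
                             dilate_rates_last_blocks = c(2, 4),
                             aspp_rates = c(1, 2, 4, 7),
                             decoder_channels = NULL,
                             num_classes = 2, input_size = 512,
                             pretrained = FALSE,
                             width_multiplier = 1,
                             blocks_per_stage = c(3, 4, 6, 3)) {
  assert_that(identical(encoder, "resnet50"), "unknown encoder",
              class = "pdl1tps_config_error")
  assert_that(length(aspp_rates) >= 2 && all(diff(aspp_rates) > 0),
              "aspp_rates must be strictly increasing",
              class = "pdl1tps_config_error")
  assert_that(input_size %% 32 == 0, "input_size must be divisible by 32",
              class = "pdl1tps_config_error")
  assert_that(length(blocks_per_stage) == 4 && all(blocks_per_stage >= 1),
              "blocks_per_stage must be 4 positive counts",
              class = "pdl1tps_config_error")
  assert_that(length(dilate_rates_last_blocks) == 2 &&
                all(dilate_rates_last_blocks >= 1),
              "dilate_rates_last_blocks must be two rates",
              class = "pdl1tps_config_error")
  assert_that(isFALSE(pretrained), "no pretrained weights are available",
              class = "pdl1tps_config_error")
  wm <- width_multiplier
  ch <- function(x) pmax(4L, as.integer(round(x * wm)))
  if (is.null(decoder_channels)) decoder_channels <- ch(c(128, 64, 32))
  structure(list(
    encoder = encoder,
    stem_channels = ch(64),
    stage_widths = ch(c(256, 512, 1024, 2048)),
    blocks_per_stage = as.integer(blocks_per_stage),
    dilate_rates_last_blocks = dilate_rates_last_blocks,
    aspp_rates = aspp_rates,
    aspp_channels = ch(64),
    decoder_channels = as.integer(decoder_channels),
    num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    pretrained = pretrained,
    width_multiplier = wm
  ), class = "seg_model_config")
}

make_bottleneck <- function(cin, width, stride, dilation) {
  mid <- max(2L, width %/% 4L)
  list(
    a = conv_param(cin, mid, 1L),
    b = conv_param(mid, mid, 3L),
    c = conv_param(mid, width, 1L, init_scale = 0.1),
    proj = if (cin != width || stride != 1) conv_param(cin, width, 1L) else NULL,
    stride = as.integer(stride), dilation = as.integer(dilation)
  )
}

bottleneck_fwd <- function(x, blk) {
  h <- op_relu(op_conv(x, blk$a))
  h <- op_relu(op_conv(h, blk$b, stride = blk$stride, dilation = blk$dilation))
  h <- op_conv(h, blk$c)
  sc <- if (is.null(blk$proj)) x else op_conv(x, blk$proj, stride = blk$stride)
  op_relu(op_add(h, sc))
}

make_stage <- function(cin, width, n_blocks, stride, dilation) {
  blocks <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    blocks[[i]] <- make_bottleneck(if (i == 1) cin else width, width,
                                   if (i == 1) stride else 1L, dilation)
  }
  blocks
}

stage_fwd <- function(x, blocks) {
  for (blk in blocks) x <- bottleneck_fwd(x, blk)
  x
}

#' Build the tumor-segmentation network
#'
#' Constructs the parameter set for the configured encoder-decoder: a two-conv
#' stride-4 stem, four bottleneck residual stages (the last two stride-free
#' with dilation rates 2 and 4, so the encoder output stride is 8), ASPP with
#' four parallel dilated convolutions, and a three-stage decoder with skip
#' connections from the stride-2 and stride-4 features back to full
#' resolution, ending in per-pixel class scores.
#'
#' @param config A [seg_model_config()].
#' @param seed Seed for weight initialization.
#' @return A `seg_model` object (parameters + architecture descriptor).
#' @export
build_res50_unet <- function(config = seg_model_config(), seed = 1L) {
  assert_that(inherits(config, "seg_model_config"),
              "config must be a seg_model_config", class = "pdl1tps_config_error")
  with_seed(seed, {
    sc <- config$stem_channels
    sw <- config$stage_widths
    dil <- config$dilate_rates_last_blocks
    dc <- config$decoder_channels
    ac <- config$aspp_channels
    net <- list(
      stem_a = conv_param(3L, sc, 3L),
      stem_b = conv_param(sc, sc, 3L),
      stage1 = make_stage(sc, sw[1], config$blocks_per_stage[1], 1L, 1L),
      stage2 = make_stage(sw[1], sw[2], config$blocks_per_stage[2], 2L, 1L),
      stage3 = make_stage(sw[2], sw[3], config$blocks_per_stage[3], 1L, dil[1]),
      stage4 = make_stage(sw[3], sw[4], config$blocks_per_stage[4], 1L, dil[2]),
      aspp = lapply(config$aspp_rates, function(r) conv_param(sw[4], ac, 3L)),
      aspp_fuse = conv_param(ac * length(config$aspp_rates), dc[1], 1L),
      dec1 = conv_param(dc[1] + sw[1], dc[1], 3L),   # /8 -> /4, skip stage1
      dec2 = conv_param(dc[1] + sc, dc[2], 3L),      # /4 -> /2, skip stem
      dec3 = conv_param(dc[2], dc[3], 3L),           # /2 -> /1
      head = conv_param(dc[3], config$num_classes, 1L)
    )
    structure(list(config = config, net = net,
                   params = collect_params(net)),
              class = "seg_model")
  })
}

seg_forward <- function(model, img) {
  net <- model$net
  x <- nn_input(img)
  s2 <- op_relu(op_conv(x, net$stem_a, stride = 2L))     # /2
  s4 <- op_relu(op_conv(s2, net$stem_b, stride = 2L))    # /4
  e1 <- stage_fwd(s4, net$stage1)                        # /4
  e2 <- stage_fwd(e1, net$stage2)                        # /8
  e3 <- stage_fwd(e2, net$stage3)                        # /8, dilated
  e4 <- stage_fwd(e3, net$stage4)                        # /8, dilated
  branches <- lapply(seq_along(net$aspp), function(i)
    op_relu(op_conv(e4, net$aspp[[i]],
                    dilation = as.integer(model$config$aspp_rates[i]))))
  asp <- branches[[1]]
  for (i in seq_along(branches)[-1]) asp <- op_concat(asp, branches[[i]])
  asp <- op_relu(op_conv(asp, net$aspp_fuse))
  d1 <- op_relu(op_conv(op_concat(op_up2(asp), e1), net$dec1))   # /4
  d2 <- op_relu(op_conv(op_concat(op_up2(d1), s2), net$dec2))    # /2
  d3 <- op_relu(op_conv(op_up2(d2), net$dec3))                   # /1
  op_conv(d3, net$head)
}

#' Number of trainable parameters of a model
#'
#' @param model A `seg_model` or `det_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  n_params(model$params)
}

#' Analytic receptive field of the segmentation encoder + ASPP path
#'
#' Computed from the architecture graph (kernel size, stride, dilation per
#' convolution along the encoder path, then the widest ASPP branch); no
#' forward pass involved.
#'
#' @param model A `seg_model`.
#' @return Receptive-field side length in input pixels.
#' @export
receptive_field <- function(model) {
  cfg <- model$config
  layers <- list(c(3, 2, 1), c(3, 2, 1))  # stem: k, stride, dilation
  add_stage <- function(layers, n_blocks, stride, dilation) {
    for (i in seq_len(n_blocks)) {
      s <- if (i == 1) stride else 1
      layers <- c(layers, list(c(1, 1, 1), c(3, s, dilation), c(1, 1, 1)))
    }
    layers
  }
  layers <- add_stage(layers, cfg$blocks_per_stage[1], 1, 1)
  layers <- add_stage(layers, cfg$blocks_per_stage[2], 2, 1)
  layers <- add_stage(layers, cfg$blocks_per_stage[3], 1, cfg$dilate_rates_last_blocks[1])
  layers <- add_stage(layers, cfg$blocks_per_stage[4], 1, cfg$dilate_rates_last_blocks[2])
  layers <- c(layers, list(c(3, 1, max(cfg$aspp_rates))))
  rf <- 1; jump <- 1
  for (l in layers) {
    rf <- rf + (l[1] - 1) * l[3] * jump
    jump <- jump * l[2]
  }
  rf
}

#' Deterministic k-fold partition of sample indices
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold assignments (1..k), each sample in exactly
#'   one fold.
#' @export
make_folds <- function(n, k, seed = 1L) {
  assert_that(k >= 2 && k <= n, "need 2 <= k <= n")
  with_seed(seed, {
    idx <- sample.int(n)
    folds <- integer(n)
    folds[idx] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Training configuration for the two networks
#'
#' @param epochs Number of passes over the training samples.
#' @param lr Adam learning rate.
#' @param batch Mini-batch size (gradient accumulation).
#' @param seed RNG seed controlling initialization, shuffling and crops.
#' @param folds Optional number of cross-validation folds.
#' @param crop Optional square crop side; when set, each epoch trains on one
#'   random crop per sample instead of the full tile.
#' @param lr_decay Factor applied to the learning rate for the final third of
#'   the epochs (1 = constant rate).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10, lr = 1e-3, batch = 4, seed = 1L,
                         folds = NULL, crop = NULL, lr_decay = 1) {
  structure(list(epochs = epochs, lr = lr, batch = batch, seed = seed,
                 folds = folds, crop = crop, lr_decay = lr_decay),
            class = "train_config")
}

epoch_lr <- function(tc, epoch) {
  if ((tc$lr_decay %||% 1) != 1 && epoch > ceiling(2 * tc$epochs / 3))
    tc$lr * tc$lr_decay else tc$lr
}

as_seg_samples <- function(samples) {
  if (is.data.frame(samples)) {
    samples <- lapply(seq_len(nrow(samples)), function(i)
      list(image = samples$image[[i]], mask = samples$mask[[i]]))
  }
  for (s in samples) {
    assert_that(!is.null(s$image) && !is.null(s$mask), "samples need image and mask")
    assert_that(all(dim(s$image)[1:2] == dim(s$mask)),
                "image and mask shapes must agree", class = "pdl1tps_format_error")
    assert_that(all(s$mask %in% c(0, 1)), "masks must be binary",
                class = "pdl1tps_format_error")
  }
  samples
}

# images enter the network as 1 - intensity so the white background maps to 0
seg_net_input <- function(img) {
  if (max(img) > 1.5) img <- img / 255
  1 - img
}

random_crop <- function(img, mask, crop) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (is.null(crop) || (crop >= h && crop >= w))
    return(list(image = img, mask = mask))
  y0 <- sample.int(h - crop + 1L, 1L) - 1L
  x0 <- sample.int(w - crop + 1L, 1L) - 1L
  list(image = img[y0 + seq_len(crop), x0 + seq_len(crop), , drop = FALSE],
       mask = mask[y0 + seq_len(crop), x0 + seq_len(crop)])
}

train_seg_once <- function(samples, config, tc, init_seed) {
  model <- build_res50_unet(config, seed = init_seed)
  zero_grads(model$params)
  metrics <- list()
  step <- 0L
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(length(samples))
    losses <- c(); accs <- c()
    bcount <- 0L
    for (si in ord) {
      s <- samples[[si]]
      cr <- random_crop(seg_net_input(s$image), s$mask, tc$crop)
      logits <- seg_forward(model, cr$image)
      loss <- loss_ce_dice(logits, cr$mask)
      nn_backward(loss)
      losses <- c(losses, loss$value)
      z <- logits$value[, , 2] - logits$value[, , 1]
      accs <- c(accs, mean((z > 0) == (cr$mask > 0)))
      bcount <- bcount + 1L
      if (bcount == tc$batch || si == ord[length(ord)]) {
        step <- step + 1L
        adam_step(model$params, epoch_lr(tc, epoch), step)
        bcount <- 0L
      }
    }
    metrics[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                       pixel_accuracy = mean(accs))
  }
  model$metrics <- dplyr::bind_rows(metrics)
  model
}

#' Train the tumor-segmentation network
#'
#' Deterministic given the seed: initialization, shuffling and crops all flow
#' from `train_config$seed`. With `folds = k`, trains one model per fold on
#' the complement, evaluates OPA on the held-out fold, and returns the model
#' with the best validation OPA together with per-fold metrics.
#'
#' @param samples List of `list(image, mask)` pairs (image H x W x 3 in
#'   `[0, 1]` at 20x, mask binary), or the tibble from
#'   [simulate_training_tiles()].
#' @param config A [seg_model_config()].
#' @param tc A [train_config()].
#' @return A `seg_model` with `$metrics` (per-epoch tibble) and, when k-fold
#'   training was used, `$fold_metrics` and `$folds`.
#' @export
train_segmentation <- function(samples, config = seg_model_config(),
                               tc = train_config()) {
  samples <- as_seg_samples(samples)
  assert_that(length(samples) >= 2, "need at least 2 samples")
  with_seed(tc$seed, {
    init_seeds <- sample.int(2^30, max(1L, tc$folds %||% 1L))
    if (is.null(tc$folds)) {
      model <- train_seg_once(samples, config, tc, init_seeds[1])
      return(model)
    }
    folds <- make_folds(length(samples), tc$folds, seed = sample.int(2^30, 1))
    best <- NULL; best_opa <- -Inf
    fold_metrics <- list()
    for (f in sort(unique(folds))) {
      m <- train_seg_once(samples[folds != f], config, tc, init_seeds[f])
      val <- samples[folds == f]
      opa <- mean(vapply(val, function(s) {
        pm <- predict_tumor_mask(m, s$image)
        overall_pixel_accuracy(pm$binary, s$mask)
      }, numeric(1)))
      fold_metrics[[f]] <- tibble::tibble(fold = f, val_opa = opa)
      if (opa > best_opa) { best_opa <- opa; best <- m }
    }
    best$fold_metrics <- dplyr::bind_rows(fold_metrics)
    best$folds <- folds
    best
  })
}

#' Predict the tumor mask of a 20x tile
#'
#' Pads the tile by reflection to a multiple of 32, runs the network, applies
#' per-pixel softmax, removes the padding and thresholds the tumor-class
#' probability.
#'
#' @param model A trained `seg_model`.
#' @param tile H x W x 3 RGB array (0..255 or `[0, 1]`).
#' @param threshold Probability threshold for the binary mask (default 0.5).
#' @return A `tumor_mask`: `prob` (matrix in `[0, 1]`), `binary`
#'   (magnification-tagged mask at 20x), `threshold`.
#' @export
predict_tumor_mask <- function(model, tile, threshold = 0.5) {
  check_rgb(tile)
  h <- dim(tile)[1]; w <- dim(tile)[2]
  hp <- 32L * ceiling(h / 32L); wp <- 32L * ceiling(w / 32L)
  x <- pad_reflect(seg_net_input(tile), hp, wp)
  logits <- seg_forward(model, x)$value
  z <- logits[, , 2] - logits[, , 1]
  prob <- (1 / (1 + exp(-z)))[seq_len(h), seq_len(w), drop = FALSE]
  structure(list(prob = prob,
                 binary = as_mask((prob >= threshold) + 0, 20),
                 threshold = threshold),
            class = "tumor_mask")
}

#' Per-pixel class probabilities of a tile
#'
#' @param model A `seg_model`.
#' @param tile H x W x 3 RGB array.
#' @return H x W x num_classes array of softmax probabilities.
#' @export
predict_class_probs <- function(model, tile) {
  check_rgb(tile)
  h <- dim(tile)[1]; w <- dim(tile)[2]
  hp <- 32L * ceiling(h / 32L); wp <- 32L * ceiling(w / 32L)
  x <- pad_reflect(seg_net_input(tile), hp, wp)
  logits <- seg_forward(model, x)$value[seq_len(h), seq_len(w), , drop = FALSE]
  mx <- apply(logits, c(1, 2), max)
  e <- exp(logits - array(mx, dim(logits)))
  tot <- apply(e, c(1, 2), sum)
  e / array(tot, dim(e))
}
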