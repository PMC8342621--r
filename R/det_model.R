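# Multi-resolution nuclei-centre detection: a U-Net-like regression network
# with downscaled copies of the input injected at the matching encoder depths
# and (optionally) deep supervision at the branch scales. The network
# regresses the repel-coded proximity map; peaks are extracted by NMS.

#' Detection model configuration
#'
#' @param input_size Nominal tile side at 40x (default 256).
#' @param resolution_branches Downscale factors of the auxiliary input
#'   branches; must start at 1 and double at each step (default `c(1, 2, 4)`).
#' @param deep_supervision Emit auxiliary outputs at the branch scales and
#'   include them in the training loss.
#' @param base_channels Width of the full-resolution level; deeper levels
#'   double it.
#' @return A `det_model_config` object.
#' @export
det_model_config <- function(input_size = 256, resolution_branches = c(1, 2, 4),
                             deep_supervision = TRUE, base_channels = 8) {
  assert_that(resolution_branches[1] == 1 &&
                all(diff(resolution_branches) > 0),
              "resolution_branches must start at 1 and be strictly increasing",
              class = "pdl1tps_config_error")
  assert_that(all(resolution_branches == 2^(seq_along(resolution_branches) - 1)),
              "resolution_branches must double at each level (dyadic pyramid)",
              class = "pdl1tps_config_error")
  structure(list(input_size = as.integer(input_size),
                 resolution_branches = as.integer(resolution_branches),
                 deep_supervision = isTRUE(deep_supervision),
                 base_channels = as.integer(base_channels)),
            class = "det_model_config")
}

#' Build the nuclei-detection network
#'
#' One encoder level per resolution branch: each level below the first fuses
#' a stride-2 projection of the previous level with a convolution of the
#' correspondingly downscaled input copy. The decoder mirrors the encoder
#' with skip connections; the main head is a full-resolution sigmoid score
#' map, and with deep supervision each coarser level contributes an auxiliary
#' sigmoid map, so the number of outputs equals the number of branches.
#'
#' @param config A [det_model_config()].
#' @param seed Seed for weight initialization.
#' @return A `det_model` object.
#' @export
build_micronet <- function(config = det_model_config(), seed = 1L) {
  assert_that(inherits(config, "det_model_config"),
              "config must be a det_model_config", class = "pdl1tps_config_error")
  with_seed(seed, {
    B <- length(config$resolution_branches)
    C <- config$base_channels * 2^(seq_len(B) - 1)
    net <- list(B = B, C = C)
    net$enc1a <- conv_param(3L, C[1], 3L)
    net$enc1b <- conv_param(C[1], C[1], 3L)
    for (i in seq_len(B)[-1]) {
      bc <- max(2L, C[i] %/% 2L)
      net[[paste0("down", i)]] <- conv_param(C[i - 1], C[i], 3L)
      net[[paste0("branch", i)]] <- conv_param(3L, bc, 3L)
      net[[paste0("enc", i)]] <- conv_param(C[i] + bc, C[i], 3L)
    }
    for (i in rev(seq_len(B - 1)))
      net[[paste0("dec", i)]] <- conv_param(C[i + 1] + C[i], C[i], 3L)
    net$head <- conv_param(C[1], 1L, 1L)
    if (config$deep_supervision) {
      for (i in seq_len(B)[-1])
        net[[paste0("aux", i)]] <- conv_param(C[i], 1L, 1L)
    }
    structure(list(config = config, net = net, params = collect_params(net)),
              class = "det_model")
  })
}

# Forward pass; returns list(main = node, aux = list of nodes coarse->fine).
det_forward <- function(model, img) {
  net <- model$net
  B <- net$B
  pyramid <- list(img)
  for (i in seq_len(B)[-1]) pyramid[[i]] <- downsample2_array(pyramid[[i - 1]])
  x <- nn_input(img)
  e <- list()
  e[[1]] <- op_relu(op_conv(op_relu(op_conv(x, net$enc1a)), net$enc1b))
  for (i in seq_len(B)[-1]) {
    dn <- op_relu(op_conv(e[[i - 1]], net[[paste0("down", i)]], stride = 2L))
    br <- op_relu(op_conv(nn_input(pyramid[[i]]), net[[paste0("branch", i)]]))
    e[[i]] <- op_relu(op_conv(op_concat(dn, br), net[[paste0("enc", i)]]))
  }
  aux <- list()
  if (model$config$deep_supervision && !is.null(net[[paste0("aux", B)]]))
    aux[[paste0("level", B)]] <- op_sigmoid(op_conv(e[[B]], net[[paste0("aux", B)]]))
  cur <- e[[B]]
  for (i in rev(seq_len(B - 1))) {
    cur <- op_relu(op_conv(op_concat(op_up2(cur), e[[i]]), net[[paste0("dec", i)]]))
    if (model$config$deep_supervision && i > 1)
      aux[[paste0("level", i)]] <- op_sigmoid(op_conv(cur, net[[paste0("aux", i)]]))
  }
  main <- op_sigmoid(op_conv(cur, net$head))
  list(main = main, aux = aux)
}

as_det_samples <- function(samples) {
  if (is.data.frame(samples)) {
    samples <- lapply(seq_len(nrow(samples)), function(i)
      list(image = samples$image[[i]], centers = samples$centers[[i]]))
  }
  for (s in samples)
    assert_that(!is.null(s$image) && !is.null(s$centers),
                "samples need image and centers")
  samples
}

#' Train the nuclei-detection network
#'
#' Targets are repel-coded proximity maps of the annotated centres; the loss
#' is a positively-weighted MSE on the main output plus half-weighted
#' auxiliary losses against downsampled targets when deep supervision is on.
#' Deterministic given `train_config$seed`.
#'
#' @param samples List of `list(image, centers)` (image H x W x 3 in `[0, 1]`
#'   at 40x; centers a data frame with 0-based `x`, `y`), or the tibble from
#'   [simulate_training_tiles()].
#' @param config A [det_model_config()].
#' @param tc A [train_config()].
#' @param repel A [repel_params()].
#' @param w_pos Weight multiplier on proximity-positive pixels in the MSE.
#' @param calibrate Calibrate the NMS operating threshold on training tiles
#'   after training (pooled-F1 maximum over a fixed grid); stored as
#'   `$nms_threshold` and used by [detect_nuclei()] unless overridden.
#' @param n_calibration Number of training tiles used for the calibration.
#' @param init_model Optional trained `det_model` to warm-start from
#'   (fine-tuning); its configuration must match `config`.
#' @return A `det_model` with `$metrics` (per-epoch loss and plain MSE) and,
#'   when calibrated, `$nms_threshold`.
#' @export
train_nuclei_detector <- function(samples, config = det_model_config(),
                                  tc = train_config(), repel = repel_params(),
                                  w_pos = 10, calibrate = TRUE,
                                  n_calibration = 8, init_model = NULL) {
  samples <- as_det_samples(samples)
  assert_that(length(samples) >= 1, "need at least 1 sample")
  B <- length(config$resolution_branches)
  with_seed(tc$seed, {
    targets <- lapply(samples, function(s)
      repel_encode(s$centers, dim(s$image)[1:2], repel))
    model <- build_micronet(config, seed = sample.int(2^30, 1))
    if (!is.null(init_model)) {
      assert_that(length(init_model$params) == length(model$params),
                  "init_model configuration does not match config",
                  class = "pdl1tps_config_error")
      for (i in seq_along(model$params))
        model$params[[i]]$value <- init_model$params[[i]]$value
    }
    zero_grads(model$params)
    metrics <- list()
    step <- 0L
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(length(samples))
      losses <- c(); mses <- c()
      bcount <- 0L
      for (si in ord) {
        img <- seg_net_input(samples[[si]]$image)
        tgt <- targets[[si]]
        if (!is.null(tc$crop) && tc$crop < dim(img)[1]) {
          y0 <- sample.int(dim(img)[1] - tc$crop + 1L, 1L) - 1L
          x0 <- sample.int(dim(img)[2] - tc$crop + 1L, 1L) - 1L
          img <- img[y0 + seq_len(tc$crop), x0 + seq_len(tc$crop), , drop = FALSE]
          tgt <- tgt[y0 + seq_len(tc$crop), x0 + seq_len(tc$crop)]
        }
        out <- det_forward(model, img)
        parts <- list(loss_wmse(out$main, tgt, w_pos))
        weights <- 1
        if (length(out$aux)) {
          t_dn <- tgt
          aux_by_level <- out$aux
          for (i in seq_len(B)[-1]) {
            t_dn <- downsample2_mean(t_dn)
            nd <- aux_by_level[[paste0("level", i)]]
            if (!is.null(nd)) {
              parts <- c(parts, list(loss_wmse(nd, t_dn, w_pos)))
              weights <- c(weights, 0.5 / length(out$aux))
            }
          }
        }
        loss <- op_scalar_combine(parts, weights)
        nn_backward(loss)
        losses <- c(losses, loss$value)
        mses <- c(mses, mean((out$main$value[, , 1] - tgt)^2))
        bcount <- bcount + 1L
        if (bcount == tc$batch || si == ord[length(ord)]) {
          step <- step + 1L
          adam_step(model$params, epoch_lr(tc, epoch), step)
          bcount <- 0L
        }
      }
      metrics[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                         mse = mean(mses))
    }
    model$metrics <- dplyr::bind_rows(metrics)
    if (calibrate) {
      model$nms_threshold <- calibrate_nms_threshold(
        model, samples[seq_len(min(n_calibration, length(samples)))])
    }
    model
  })
}

# Operating-point calibration: pooled TP/FP/FN over the calibration tiles at
# each candidate threshold; the threshold with the best pooled F1 wins (ties
# go to the lower threshold).
calibrate_nms_threshold <- function(model, samples,
                                    grid = seq(0.1, 0.7, by = 0.05),
                                    min_distance = 5) {
  tallies <- matrix(0, nrow = length(grid), ncol = 3,
                    dimnames = list(NULL, c("tp", "fp", "fn")))
  for (s in samples) {
    sc <- predict_nuclei_scores(model, s$image)
    pts <- nms_points(sc, nms_params(min_distance = min_distance,
                                     score_threshold = min(grid)))
    for (k in seq_along(grid)) {
      m <- match_detections(pts[pts$confidence >= grid[k], , drop = FALSE],
                            s$centers, 10)
      tallies[k, ] <- tallies[k, ] + c(m$tp, m$fp, m$fn)
    }
  }
  f1 <- 2 * tallies[, "tp"] /
    pmax(2 * tallies[, "tp"] + tallies[, "fp"] + tallies[, "fn"], 1)
  grid[which.max(f1)]
}

#' Predict the nucleus-proximity score map of a 40x tile
#'
#' @param model A trained `det_model`.
#' @param tile H x W x 3 RGB array (0..255 or `[0, 1]`).
#' @return Matrix of scores in `[0, 1]` the size of the tile.
#' @export
predict_nuclei_scores <- function(model, tile) {
  check_rgb(tile)
  f <- 2^(length(model$config$resolution_branches) - 1)
  h <- dim(tile)[1]; w <- dim(tile)[2]
  hp <- f * ceiling(h / f); wp <- f * ceiling(w / f)
  x <- pad_reflect(seg_net_input(tile), hp, wp)
  det_forward(model, x)$main$value[seq_len(h), seq_len(w), 1]
}

#' Detect nucleus centres in a 40x tile
#'
#' Runs the network and extracts peaks by greedy NMS. By default the score
#' threshold is the model's training-calibrated operating point (when
#' available), falling back to the [nms_params()] default.
#'
#' @param model A trained `det_model`.
#' @param tile H x W x 3 RGB array.
#' @param nms An [nms_params()], or `NULL` for the calibrated default.
#' @return Tibble with `x`, `y` (0-based), `confidence`.
#' @export
detect_nuclei <- function(model, tile, nms = NULL) {
  if (is.null(nms)) {
    nms <- nms_params(score_threshold = model$nms_threshold %||%
                        nms_params()$score_threshold)
  }
  nms_points(predict_nuclei_scores(model, tile), nms)
}
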