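# Whole-image orchestration: deterministic tiling with reflection padding,
# per-tile inference at the correct magnifications (tumor mask at 20x,
# positive membrane and nuclei at 40x), overlap-aware deduplication of
# detections, and aggregation into the slide-level TPS.

#' Build a deterministic row-major tile grid
#'
#' Tiles are 0-based half-open rectangles `[x, x + w) x [y, y + h)` laid out
#' with stride `tile_size - overlap`. Tiles extending past the image are
#' padded by reflection at extraction time; each tile also carries its "core"
#' rectangle (the overlap halved between neighbours), and the cores partition
#' the image, which is what detection deduplication keys on.
#'
#' @param dim_hw Image size `c(height, width)` in px.
#' @param tile_size Square tile side in px.
#' @param overlap Overlap between adjacent tiles in px (`0 <= overlap <
#'   tile_size`).
#' @return A `tile_grid`: tibble with `tile_id`, `x0`, `y0`, `w`, `h`,
#'   `core_x0`, `core_y0`, `core_x1`, `core_y1` plus grid attributes.
#' @export
tile_image <- function(dim_hw, tile_size, overlap = 0) {
  assert_that(tile_size > overlap && overlap >= 0,
              "need tile_size > overlap >= 0", class = "pdl1tps_param_error")
  h <- dim_hw[1]; w <- dim_hw[2]
  stride <- tile_size - overlap
  ys <- seq(0, max(0, h - 1), by = stride)
  ys <- ys[ys < h]
  xs <- seq(0, max(0, w - 1), by = stride)
  xs <- xs[xs < w]
  half <- overlap / 2
  # cores split the overlap midway between neighbouring origins and clamp to
  # the image; they partition [0,w) x [0,h) (edge tiles may get empty cores)
  core_lo <- function(orig, i) if (i == 1) 0 else orig[i] + half
  core_hi <- function(orig, i, lim) {
    if (i == length(orig)) lim else min(orig[i + 1] + half, lim)
  }
  grid <- expand.grid(iy = seq_along(ys), ix = seq_along(xs))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ix <- grid$ix[i]; iy <- grid$iy[i]
    cx0 <- min(core_lo(xs, ix), w)
    cy0 <- min(core_lo(ys, iy), h)
    cx1 <- core_hi(xs, ix, w)
    cy1 <- core_hi(ys, iy, h)
    tibble::tibble(x0 = xs[ix], y0 = ys[iy], w = tile_size, h = tile_size,
                   core_x0 = cx0, core_y0 = cy0,
                   core_x1 = cx1, core_y1 = cy1)
  })
  out <- dplyr::bind_rows(rows)
  out$tile_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "tile_id")
  attr(out, "image_dim") <- c(h, w)
  attr(out, "tile_size") <- tile_size
  attr(out, "overlap") <- overlap
  class(out) <- c("tile_grid", class(out))
  out
}

# Extract one tile (reflection-padded at image edges) from a matrix or array.
extract_tile <- function(img, x0, y0, size) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  ridx <- y0 + seq_len(size)
  cidx <- x0 + seq_len(size)
  ridx <- ifelse(ridx > h, 2 * h - ridx + 1, ridx)
  cidx <- ifelse(cidx > w, 2 * w - cidx + 1, cidx)
  ridx <- clamp(ridx, 1, h); cidx <- clamp(cidx, 1, w)
  if (length(d) == 2) img[ridx, cidx, drop = FALSE]
  else img[ridx, cidx, , drop = FALSE]
}

#' Pipeline parameters
#'
#' @param membrane [membrane_params()].
#' @param nms [nms_params()], or `NULL` to use the detector's calibrated
#'   operating threshold.
#' @param rho Scoring-disc radius at 40x for [classify_nuclei()].
#' @param seg_threshold Tumor-probability threshold.
#' @param tile_size_20x,tile_size_40x Tile sides at the two levels.
#' @param overlap_40x Detection-tile overlap at 40x in px.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(membrane = membrane_params(), nms = NULL,
                            rho = 8, seg_threshold = 0.5,
                            tile_size_20x = 512, tile_size_40x = 256,
                            overlap_40x = 0) {
  structure(list(membrane = membrane, nms = nms, rho = rho,
                 seg_threshold = seg_threshold,
                 tile_size_20x = tile_size_20x, tile_size_40x = tile_size_40x,
                 overlap_40x = overlap_40x),
            class = "pipeline_params")
}

slide_images <- function(slide) {
  if (inherits(slide, "synthetic_slide"))
    return(list(rgb20 = slide$rgb20, rgb40 = slide$rgb40))
  if (is.list(slide) && !is.null(slide$rgb20) && !is.null(slide$rgb40))
    return(slide)
  if (is.character(slide) && length(slide) == 2)
    return(list(rgb20 = read_rgb_png(slide[1]), rgb40 = read_rgb_png(slide[2])))
  abort("slide must be a synthetic_slide, a list(rgb20, rgb40), or two PNG paths",
        class = "pdl1tps_format_error")
}

#' Run the full scoring pipeline on a slide
#'
#' In `"full"` mode the three stages run on image tiles: the segmentation
#' model predicts the viable-tumor mask on 20x tiles, the unsupervised
#' membrane detector produces the positive-stain mask on 40x tiles, and the
#' detection model finds nucleus centres on (optionally overlapping) 40x
#' tiles, keeping each detection only if it falls in its tile's core so
#' overlap-zone nuclei are counted exactly once. Detected points are then
#' labelled against the two masks and aggregated into the slide TPS.
#'
#' In `"oracle"` mode the planted truth masks and centres of a synthetic
#' slide are injected instead of model predictions, which isolates the
#' scoring stage: the result reproduces the slide's realized TPS.
#'
#' @param slide A `synthetic_slide`, a `list(rgb20, rgb40)` of arrays, or a
#'   length-2 character vector of PNG paths (20x, 40x).
#' @param models `list(seg =, det =)` trained models (full mode).
#' @param params A [pipeline_params()].
#' @param mode `"full"` or `"oracle"`.
#' @param stains A [stain_model()].
#' @param out_dir Optional directory; when set, masks (PNG), points (CSV),
#'   the result (JSON) and an overlay (PNG) are written there.
#' @param use_truth_masks Oracle-mode switch; `use_truth_masks = FALSE`
#'   scores the truth points without the tumor mask applied (every point
#'   treated as tumor), which exposes the histiocyte failure mode.
#' @return A `tps_result` with extra fields: `tumor_mask20`, `positive_mask40`,
#'   `points`.
#' @export
run_pipeline <- function(slide, models = NULL, params = pipeline_params(),
                         mode = c("full", "oracle"), stains = stain_model(),
                         out_dir = NULL, use_truth_masks = TRUE) {
  mode <- match.arg(mode)
  imgs <- slide_images(slide)
  h40 <- dim(imgs$rgb40)[1]; w40 <- dim(imgs$rgb40)[2]

  if (mode == "oracle") {
    assert_that(inherits(slide, "synthetic_slide"),
                "oracle mode needs a synthetic_slide with truth")
    tumor20 <- if (use_truth_masks) slide$tumor_mask20
      else as_mask(matrix(1, dim(imgs$rgb20)[1], dim(imgs$rgb20)[2]), 20)
    pos40 <- slide$membrane_mask40
    points <- slide$nuclei[, c("x", "y")]
    points$confidence <- 1
  } else {
    assert_that(!is.null(models$seg) && !is.null(models$det),
                "full mode needs models = list(seg =, det =)",
                class = "pdl1tps_config_error")
    # tumor mask at 20x
    grid20 <- tile_image(dim(imgs$rgb20)[1:2], params$tile_size_20x, 0)
    prob20 <- matrix(0, dim(imgs$rgb20)[1], dim(imgs$rgb20)[2])
    for (i in seq_len(nrow(grid20))) {
      g <- grid20[i, ]
      tl <- extract_tile(imgs$rgb20, g$x0, g$y0, params$tile_size_20x)
      pm <- predict_tumor_mask(models$seg, tl, params$seg_threshold)
      ys <- g$y0 + seq_len(min(params$tile_size_20x, nrow(prob20) - g$y0))
      xs <- g$x0 + seq_len(min(params$tile_size_20x, ncol(prob20) - g$x0))
      prob20[ys, xs] <- pm$prob[seq_along(ys), seq_along(xs)]
    }
    tumor20 <- as_mask((prob20 >= params$seg_threshold) + 0, 20)

    # positive membrane + nuclei at 40x
    grid40 <- tile_image(c(h40, w40), params$tile_size_40x, params$overlap_40x)
    pos40m <- matrix(0, h40, w40)
    pts <- list()
    for (i in seq_len(nrow(grid40))) {
      g <- grid40[i, ]
      tl <- extract_tile(imgs$rgb40, g$x0, g$y0, params$tile_size_40x)
      mem <- detect_positive_membrane(tl, stains, params$membrane)
      ys <- g$y0 + seq_len(min(params$tile_size_40x, h40 - g$y0))
      xs <- g$x0 + seq_len(min(params$tile_size_40x, w40 - g$x0))
      pos40m[ys, xs] <- pmax(pos40m[ys, xs],
                             unclass(mem)[seq_along(ys), seq_along(xs)])
      det <- detect_nuclei(models$det, tl, params$nms)
      if (nrow(det)) {
        det$x <- det$x + g$x0
        det$y <- det$y + g$y0
        keep <- det$x >= g$core_x0 & det$x < g$core_x1 &
          det$y >= g$core_y0 & det$y < g$core_y1
        pts[[length(pts) + 1L]] <- det[keep, ]
      }
    }
    pos40 <- as_mask(pos40m, 40)
    points <- if (length(pts)) dplyr::bind_rows(pts)
      else tibble::tibble(x = numeric(0), y = numeric(0), confidence = numeric(0))
  }

  labeled <- classify_nuclei(points, tumor20, pos40, params$rho)
  result <- score_points(labeled)
  result$tumor_mask20 <- tumor20
  result$positive_mask40 <- pos40
  result$points <- labeled

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mask_png(tumor20, file.path(out_dir, "tumor_mask_20x.png"))
    write_mask_png(pos40, file.path(out_dir, "positive_mask_40x.png"))
    write_points_csv(labeled, file.path(out_dir, "points.csv"))
    write_tps_json(result, file.path(out_dir, "result.json"))
    ov <- overlay_plot(imgs$rgb40, labeled)
    ggplot2::ggsave(file.path(out_dir, "overlay.png"), ov,
                    width = 6, height = 6, dpi = 150)
  }
  result
}
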