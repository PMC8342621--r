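# Synthetic H-DAB histology generator.
#
# Emulates PD-L1 (22C3) IHC tiles: cohesive tumor nests carved from smoothed
# Gaussian noise fields, hematoxylin-stained elliptical nuclei (tumor inside
# nests, stromal/immune scattered outside), DAB membrane rings (full or
# partial arcs) on PD-L1-positive tumor cells, optional necrotic regions with
# diffuse weak DAB, Beer-Lambert rendering through the stain model, camera
# noise, and 2x downsampling for the 20x level. Every slide carries complete
# ground truth: masks, nucleus centres with labels, and the realized TPS.

#' Specification of a synthetic H-DAB pseudo-slide
#'
#' All randomness flows from `seed`; identical specs render bit-identical
#' slides. Geometry is expressed at 40x (0.2375 um/px); the 20x level is a
#' 2x downsample.
#'
#' @param seed Integer RNG seed.
#' @param size Canvas side at 40x in px (multiple of 4; default 1024, i.e. a
#'   512 px 20x level).
#' @param n_nests Number of tumor nests to keep.
#' @param nest_scale Correlation length of the nest shape field in px.
#' @param tumor_fraction Target canvas fraction covered by nests.
#' @param tumor_spacing Minimum distance between tumor nucleus centres in px
#'   (approximately one cell diameter; controls tumor cell density).
#' @param stromal_spacing Minimum distance between stromal/immune nuclei.
#' @param planted_tps Probability (in %) that a tumor cell is PD-L1 positive.
#' @param partial_membrane_fraction Fraction of positive cells rendered with a
#'   partial (arc) membrane instead of a complete ring.
#' @param dab_od,hema_od Ranges (length 2) of per-cell DAB / hematoxylin
#'   optical densities.
#' @param necrosis_fraction Fraction of nest area rendered necrotic (diffuse
#'   weak DAB, no nuclei, excluded from the viable-tumor mask).
#' @param immune_positive_rate Fraction of stromal cells rendered with a
#'   PD-L1-positive membrane (the documented histiocyte failure mode); such
#'   cells are planted well outside nests.
#' @param noise_sd Gaussian camera noise sd on the 0..255 intensity scale.
#' @param blur_sigma Optional Gaussian blur sigma (px) applied before noise.
#' @param neg_pos_ratio Length-2 integer ratio of negative to positive slides
#'   used when emitting training datasets (default `c(3, 7)`).
#' @return A `synthetic_slide_spec` object.
#' @export
synthetic_slide_spec <- function(seed = 1L, size = 1024L, n_nests = 4,
                                 nest_scale = 160, tumor_fraction = 0.45,
                                 tumor_spacing = 20, stromal_spacing = 14,
                                 planted_tps = 50,
                                 partial_membrane_fraction = 0.3,
                                 dab_od = c(0.55, 0.95),
                                 hema_od = c(0.45, 0.75),
                                 necrosis_fraction = 0,
                                 immune_positive_rate = 0,
                                 noise_sd = 3, blur_sigma = 0,
                                 neg_pos_ratio = c(3, 7)) {
  assert_that(planted_tps >= 0 && planted_tps <= 100,
              "planted_tps must lie in [0, 100]")
  assert_that(size %% 4 == 0 && size >= 128, "size must be a multiple of 4, >= 128")
  assert_that(tumor_spacing > 0 && stromal_spacing > 0, "spacings must be > 0")
  assert_that(tumor_fraction > 0 && tumor_fraction < 1,
              "tumor_fraction must be in (0, 1)")
  assert_that(all(neg_pos_ratio > 0) && length(neg_pos_ratio) == 2,
              "neg_pos_ratio components must be positive")
  assert_that(necrosis_fraction >= 0 && necrosis_fraction < 1,
              "necrosis_fraction must be in [0, 1)")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_nests = n_nests, nest_scale = nest_scale,
                 tumor_fraction = tumor_fraction,
                 tumor_spacing = tumor_spacing,
                 stromal_spacing = stromal_spacing,
                 planted_tps = planted_tps,
                 partial_membrane_fraction = partial_membrane_fraction,
                 dab_od = dab_od, hema_od = hema_od,
                 necrosis_fraction = necrosis_fraction,
                 immune_positive_rate = immune_positive_rate,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 neg_pos_ratio = neg_pos_ratio),
            class = "synthetic_slide_spec")
}

# Smoothed Gaussian noise field (circular boundary), standardized.
smooth_field <- function(h, w, sigma) {
  f <- matrix(rnorm(h * w), h, w)
  f <- EBImage::filter2(f, gaussian_kernel2d(sigma, radius = ceiling(3 * sigma)),
                        boundary = "circular")
  (f - mean(f)) / stats::sd(f)
}

# Keep the n largest connected components of a binary matrix.
keep_largest <- function(mask, n) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= n) return(mask)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- order(areas, decreasing = TRUE)[seq_len(n)]
  (matrix(lab %in% keep, nrow(mask), ncol(mask))) + 0
}

# Hard-core point placement: a jittered square lattice whose pitch/jitter
# combination guarantees the minimum spacing exactly (pitch - 2*jitter >=
# spacing), restricted to `mask` pixels at least `margin` px inside the
# canvas. Quasi-regular packing approximates touching cells in a nest.
place_points <- function(mask, spacing, margin) {
  h <- nrow(mask); w <- ncol(mask)
  pitch <- ceiling(spacing * 1.35)
  jit <- max(0L, floor((pitch - spacing) / 2))
  gx <- seq(margin, w - margin - 1, by = pitch)
  gy <- seq(margin, h - margin - 1, by = pitch)
  if (!length(gx) || !length(gy)) return(matrix(numeric(0), 0, 2))
  grid <- expand.grid(x = gx, y = gy)
  n <- nrow(grid)
  x <- grid$x + sample.int(2L * jit + 1L, n, replace = TRUE) - jit - 1L
  y <- grid$y + sample.int(2L * jit + 1L, n, replace = TRUE) - jit - 1L
  ok <- x >= margin & x < w - margin & y >= margin & y < h - margin
  x <- x[ok]; y <- y[ok]
  keep <- mask[cbind(y + 1L, x + 1L)] > 0
  cbind(x = x[keep], y = y[keep])
}

# Squared elliptical norm of bbox pixel offsets for an ellipse with semi-axes
# (a, b) rotated by theta; <= 1 is inside.
ellipse_q <- function(dx, dy, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  u^2 + v^2
}

# Linear indices (into an n x n matrix) of the bbox pixels selected by `sel`;
# rows/cols are 1-based index vectors, sel a logical matrix over the bbox.
bbox_indices <- function(rows, cols, sel, n) {
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  (cc[sel] - 1L) * n + rr[sel]
}

#' Generate a synthetic pseudo-slide with complete ground truth
#'
#' Renders the scene described by the slide spec object and returns the RGB
#' images at 40x
#' and 20x together with the planted truth: viable-tumor masks at both levels,
#' the positive-membrane mask at 40x, the nucleus table with
#' `(x, y, is_tumor, is_positive)` at 40x (0-based pixel coordinates), the
#' planted DAB concentration field, and the realized TPS
#' `100 * n_positive_tumor / n_tumor`.
#'
#' @param spec A [synthetic_slide_spec()].
#' @return A `synthetic_slide` object.
#' @export
generate_slide <- function(spec = synthetic_slide_spec()) {
  assert_that(inherits(spec, "synthetic_slide_spec"),
              "spec must be a synthetic_slide_spec")
  with_seed(spec$seed, generate_slide_impl(spec))
}

generate_slide_impl <- function(spec) {
  n <- spec$size
  margin <- 12L

  # --- tumor nests -----------------------------------------------------------
  field <- smooth_field(n, n, spec$nest_scale / 4)
  thr <- quantile(field, 1 - spec$tumor_fraction, names = FALSE)
  nests <- keep_largest((field > thr) + 0, spec$n_nests)

  # --- necrosis (non-viable, diffuse weak DAB, no nuclei) --------------------
  necrosis <- matrix(0, n, n)
  if (spec$necrosis_fraction > 0) {
    nf <- smooth_field(n, n, spec$nest_scale / 8)
    vals <- nf[nests > 0]
    nthr <- quantile(vals, 1 - spec$necrosis_fraction, names = FALSE)
    necrosis <- ((nf > nthr) & (nests > 0)) + 0
  }
  viable <- ((nests > 0) & (necrosis == 0)) + 0

  # --- nucleus placement -----------------------------------------------------
  tumor_xy <- place_points(viable, spec$tumor_spacing, margin)
  if (nrow(tumor_xy) == 0)
    abort("spec produced zero tumor nuclei; increase tumor_fraction or density",
          class = "pdl1tps_error")
  dist_to_nest <- EBImage::distmap(1 - nests)
  stroma_ok <- (nests == 0) & (dist_to_nest >= 4)
  stromal_xy <- place_points(stroma_ok + 0, spec$stromal_spacing, margin)

  n_t <- nrow(tumor_xy); n_s <- nrow(stromal_xy)
  tumor_pos <- runif(n_t) < spec$planted_tps / 100
  # immune-positive stromal cells only far from nests, so their membranes can
  # never fall inside a tumor cell's scoring disc
  stromal_pos <- rep(FALSE, n_s)
  if (spec$immune_positive_rate > 0 && n_s > 0) {
    far <- dist_to_nest[cbind(stromal_xy[, "y"] + 1L, stromal_xy[, "x"] + 1L)] >= 20
    stromal_pos <- (runif(n_s) < spec$immune_positive_rate) & far
  }

  # --- per-nucleus geometry --------------------------------------------------
  gap <- 0.5
  t_a <- runif(n_t, 4, 7)                       # semi-major: long axis 8-14 px
  t_b <- t_a * runif(n_t, 0.75, 0.95)
  t_th <- runif(n_t, 0, pi)
  t_hema <- runif(n_t, spec$hema_od[1], spec$hema_od[2])
  t_dab <- runif(n_t, spec$dab_od[1], spec$dab_od[2])
  t_thick <- runif(n_t, 3, 4)
  t_partial <- runif(n_t) < spec$partial_membrane_fraction
  t_arc_c <- runif(n_t, -pi, pi)
  t_arc_s <- runif(n_t, 140, 300) * pi / 180
  s_a <- runif(n_s, 3, 4.5)
  s_b <- s_a * runif(n_s, 0.75, 0.95)
  s_th <- runif(n_s, 0, pi)
  s_hema <- runif(n_s, spec$hema_od[1], spec$hema_od[2])
  s_dab <- runif(n_s, spec$dab_od[1], spec$dab_od[2])
  s_thick <- runif(n_s, 3, 4)

  hema <- matrix(0, n, n)
  dab <- matrix(0, n, n)
  membrane <- matrix(0, n, n)
  rho <- 8  # scoring-disc radius the truth guarantees a membrane pixel within

  # nucleus geometry: index lists computed per cell, fields updated in place
  nucleus_idx <- function(x, y, a, b, theta) {
    r <- ceiling(a) + 1L
    rows <- max(1L, y + 1L - r):min(n, y + 1L + r)
    cols <- max(1L, x + 1L - r):min(n, x + 1L + r)
    dy <- outer(rows - 1L - y, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - 1L - x)
    sel <- ellipse_q(dx, dy, a, b, theta) <= 1
    bbox_indices(rows, cols, sel, n)
  }

  ring_idx <- function(x, y, a, b, theta, thick, partial, arc_c, arc_s) {
    r <- ceiling(a + gap + thick) + 1L
    rows <- max(1L, y + 1L - r):min(n, y + 1L + r)
    cols <- max(1L, x + 1L - r):min(n, x + 1L + r)
    dy <- outer(rows - 1L - y, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - 1L - x)
    q_in <- ellipse_q(dx, dy, a + gap, b + gap, theta)
    q_out <- ellipse_q(dx, dy, a + gap + thick, b + gap + thick, theta)
    sel <- (q_out <= 1) & (q_in > 1)
    if (partial) {
      ang <- atan2(dy, dx)
      dd <- abs(((ang - arc_c + pi) %% (2 * pi)) - pi)
      sel <- sel & (dd <= arc_s / 2)
    }
    idx <- bbox_indices(rows, cols, sel, n)
    # invariant: the cell keeps >= 1 membrane pixel within the scoring disc
    if (!any(sel & (dx^2 + dy^2 <= rho^2))) {
      px <- clamp(round(x - sin(theta) * (b + gap + thick / 2)), 0, n - 1)
      py <- clamp(round(y + cos(theta) * (b + gap + thick / 2)), 0, n - 1)
      idx <- c(idx, px * n + py + 1L)
    }
    idx
  }

  for (i in seq_len(n_t)) {
    id <- nucleus_idx(tumor_xy[i, "x"], tumor_xy[i, "y"], t_a[i], t_b[i], t_th[i])
    hema[id] <- pmax(hema[id], t_hema[i])
    if (tumor_pos[i]) {
      id <- ring_idx(tumor_xy[i, "x"], tumor_xy[i, "y"], t_a[i], t_b[i], t_th[i],
                     t_thick[i], t_partial[i], t_arc_c[i], t_arc_s[i])
      dab[id] <- pmax(dab[id], t_dab[i])
      membrane[id] <- 1
    }
  }
  for (i in seq_len(n_s)) {
    id <- nucleus_idx(stromal_xy[i, "x"], stromal_xy[i, "y"], s_a[i], s_b[i], s_th[i])
    hema[id] <- pmax(hema[id], s_hema[i])
    if (stromal_pos[i]) {
      id <- ring_idx(stromal_xy[i, "x"], stromal_xy[i, "y"], s_a[i], s_b[i], s_th[i],
                     s_thick[i], FALSE, 0, 0)
      dab[id] <- pmax(dab[id], s_dab[i])
      membrane[id] <- 1
    }
  }

  # faint cytoplasmic hematoxylin wash: nests slightly stronger than stroma
  tex <- smooth_field(n, n, 8)
  wash <- 0.02 + 0.06 * (nests > 0) + 0.01 * tex
  hema <- pmax(hema, clamp(wash, 0, 0.1))

  if (spec$necrosis_fraction > 0 && any(necrosis > 0)) {
    ntex <- 0.5 + 0.5 * clamp(0.5 + 0.25 * smooth_field(n, n, 12), 0, 1)
    dab <- pmax(dab, 0.12 * ntex * necrosis)
  }

  conc <- array(0, c(n, n, 3))
  conc[, , 1] <- hema
  conc[, , 2] <- dab
  sm <- stain_model()
  rgb40f <- od_to_rgb(conc, sm)
  if (spec$blur_sigma > 0) {
    k <- gaussian_kernel2d(spec$blur_sigma)
    for (c in 1:3) rgb40f[, , c] <- filter2_replicate(rgb40f[, , c], k)
  }
  rgb20f <- downsample2_array(rgb40f)
  quantize <- function(img, sd) {
    if (sd > 0) img <- img + array(rnorm(length(img), 0, sd), dim(img))
    round(clamp(img, 0, 255))
  }
  rgb40 <- quantize(rgb40f, spec$noise_sd)
  rgb20 <- quantize(rgb20f, spec$noise_sd)

  nuclei <- tibble::tibble(
    x = c(tumor_xy[, "x"], stromal_xy[, "x"]),
    y = c(tumor_xy[, "y"], stromal_xy[, "y"]),
    is_tumor = c(rep(TRUE, n_t), rep(FALSE, n_s)),
    is_positive = c(tumor_pos, stromal_pos)
  )
  realized_tps <- 100 * sum(tumor_pos) / n_t

  structure(list(
    spec = spec,
    rgb40 = rgb40, rgb20 = rgb20,
    tumor_mask40 = as_mask(viable, 40),
    tumor_mask20 = as_mask(downsample2_max(viable), 20),
    membrane_mask40 = as_mask(membrane, 40),
    nuclei = nuclei,
    realized_tps = realized_tps,
    dab_conc40 = dab, hema_conc40 = hema
  ), class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %dpx @40x, %d tumor / %d stromal nuclei, realized TPS %.2f%%\n",
              x$spec$size, sum(x$nuclei$is_tumor), sum(!x$nuclei$is_tumor),
              x$realized_tps))
  invisible(x)
}

# Crop a det-style training tile (256 @40x) from a slide; returns image in
# [0,1], centres shifted to tile coordinates, truth membrane/tumor crops.
crop_det_tile <- function(slide, x0, y0, size = 256L) {
  rows <- (y0 + 1L):(y0 + size)
  cols <- (x0 + 1L):(x0 + size)
  img <- slide$rgb40[rows, cols, , drop = FALSE] / 255
  keep <- slide$nuclei$x >= x0 & slide$nuclei$x < x0 + size &
    slide$nuclei$y >= y0 & slide$nuclei$y < y0 + size
  centers <- slide$nuclei[keep, ]
  centers$x <- centers$x - x0
  centers$y <- centers$y - y0
  list(image = img, centers = centers,
       membrane = slide$membrane_mask40[rows, cols],
       tumor = slide$tumor_mask40[rows, cols])
}

#' Simulate training tiles for the segmentation or detection model
#'
#' Draws pseudo-slides and crops them into the two patch formats the pipeline
#' trains on: 512x512 RGB + binary tumor mask at 20x (`kind = "seg"`), or
#' 256x256 RGB + nucleus-centre table at 40x (`kind = "det"`). Slides are
#' PD-L1-negative (planted TPS 0) or positive (planted TPS drawn uniformly
#' from `tps_range`) in the base spec object's negative:positive ratio.
#'
#' @param n Number of tiles.
#' @param kind `"seg"` or `"det"`.
#' @param seed Master seed; per-slide seeds are derived from it.
#' @param base_spec Template [synthetic_slide_spec()]; its seed/planted TPS are
#'   overridden per slide.
#' @param tps_range Range of planted TPS for positive slides.
#' @return A tibble with one row per tile: `tile_id`, `kind`, `slide_seed`,
#'   `planted_tps`, `realized_tps`, and list-columns `image` (float array in
#'   `[0,1]`) plus `mask` (seg) or `centers` (det).
#' @export
simulate_training_tiles <- function(n, kind = c("seg", "det"), seed = 1L,
                                    base_spec = synthetic_slide_spec(),
                                    tps_range = c(10, 90)) {
  kind <- match.arg(kind)
  ratio <- base_spec$neg_pos_ratio
  n_neg <- round(n * ratio[1] / sum(ratio))
  per_slide <- if (kind == "seg") 1L else 8L
  with_seed(seed, {
    rows <- list()
    made <- 0L
    slide_i <- 0L
    slide_seeds <- sample.int(2^30, 2L * ceiling(n / per_slide) + 8L)
    while (made < n) {
      slide_i <- slide_i + 1L
      negative <- made < n_neg
      tps <- if (negative) 0 else runif(1, tps_range[1], tps_range[2])
      sp <- base_spec
      sp$seed <- slide_seeds[slide_i]
      sp$planted_tps <- tps
      slide <- generate_slide(sp)
      if (kind == "seg") {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = "seg", slide_seed = sp$seed,
          planted_tps = tps, realized_tps = slide$realized_tps,
          image = list(slide$rgb20 / 255),
          mask = list(unclass(slide$tumor_mask20)[, ]),
          centers = list(NULL))
        made <- made + 1L
      } else {
        grid_n <- sp$size %/% 256L
        origins <- expand.grid(x0 = (seq_len(grid_n) - 1L) * 256L,
                               y0 = (seq_len(grid_n) - 1L) * 256L)
        take_n <- min(per_slide, n - made, nrow(origins))
        if (negative) take_n <- min(take_n, n_neg - made)
        take <- origins[sample.int(nrow(origins), take_n), , drop = FALSE]
        for (k in seq_len(nrow(take))) {
          tl <- crop_det_tile(slide, take$x0[k], take$y0[k])
          rows[[length(rows) + 1L]] <- tibble::tibble(
            kind = "det", slide_seed = sp$seed,
            planted_tps = tps, realized_tps = slide$realized_tps,
            image = list(tl$image), mask = list(NULL),
            centers = list(tl$centers))
          made <- made + 1L
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    out$tile_id <- seq_len(nrow(out))
    dplyr::relocate(out, "tile_id")
  })
}

#' Write training datasets to disk
#'
#' Emits the two patch datasets as plain files: seg tiles as paired PNG
#' image/mask files, det tiles as PNG images plus `x,y,confidence,is_tumor,
#' is_positive` CSV centre lists, and a manifest CSV recording seeds and
#' planted parameters. Re-running with the same arguments reproduces the
#' files byte-identically.
#'
#' @param dir Output directory (created if needed).
#' @param n_seg,n_det Numbers of segmentation / detection tiles.
#' @param seed Master seed.
#' @param base_spec Template [synthetic_slide_spec()].
#' @return The manifest tibble, invisibly.
#' @export
emit_training_sets <- function(dir, n_seg = 32, n_det = 64, seed = 1L,
                               base_spec = synthetic_slide_spec()) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  assert_that(ok, sprintf("cannot create directory '%s'", dir),
              class = "pdl1tps_io_error")
  for (d in c("seg/images", "seg/masks", "det/images", "det/centers"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  seg <- simulate_training_tiles(n_seg, "seg", seed = seed, base_spec = base_spec)
  det <- simulate_training_tiles(n_det, "det", seed = seed + 1L, base_spec = base_spec)
  manifest <- list()
  for (i in seq_len(nrow(seg))) {
    id <- sprintf("seg_%04d", i)
    write_rgb_png(seg$image[[i]] * 255, file.path(dir, "seg/images", paste0(id, ".png")))
    write_mask_png(seg$mask[[i]], file.path(dir, "seg/masks", paste0(id, ".png")))
    manifest[[length(manifest) + 1L]] <- tibble::tibble(
      tile_id = id, kind = "seg", slide_seed = seg$slide_seed[i],
      planted_tps = seg$planted_tps[i], realized_tps = seg$realized_tps[i])
  }
  for (i in seq_len(nrow(det))) {
    id <- sprintf("det_%04d", i)
    write_rgb_png(det$image[[i]] * 255, file.path(dir, "det/images", paste0(id, ".png")))
    write_points_csv(det$centers[[i]], file.path(dir, "det/centers", paste0(id, ".csv")))
    manifest[[length(manifest) + 1L]] <- tibble::tibble(
      tile_id = id, kind = "det", slide_seed = det$slide_seed[i],
      planted_tps = det$planted_tps[i], realized_tps = det$realized_tps[i])
  }
  manifest <- dplyr::bind_rows(manifest)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
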