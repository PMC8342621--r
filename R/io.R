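# Readers/writers for the pipeline's plain-file interfaces: PNG rasters,
# point CSVs, TPS result JSON, and YAML parameter files.

#' Raster and point-set IO
#'
#' RGB images are stored as ordinary PNG (values 0..255); masks as grayscale
#' PNG with 0/1 levels; nucleus points as CSV with columns
#' `x,y,confidence,is_tumor,is_positive` (coordinates 0-based, x rightward,
#' y downward, pixel-centre convention).
#'
#' @param img H x W x 3 RGB array on the 0..255 scale.
#' @param mask Binary matrix.
#' @param points Tibble of nucleus points.
#' @param path File path.
#' @param magnification Magnification tag attached to masks on read.
#' @name pdl1tps-io
NULL

#' @rdname pdl1tps-io
#' @export
write_rgb_png <- function(img, path) {
  check_rgb(img)
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' @rdname pdl1tps-io
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' @rdname pdl1tps-io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) + 0, path)
  invisible(path)
}

#' @rdname pdl1tps-io
#' @export
read_mask_png <- function(path, magnification = NULL) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m <- (m > 0.5) + 0
  if (!is.null(magnification)) m <- as_mask(m, magnification)
  m
}

#' @rdname pdl1tps-io
#' @export
write_points_csv <- function(points, path) {
  pts <- tibble::as_tibble(points)
  if (!"confidence" %in% names(pts)) pts$confidence <- 1
  if (!"is_tumor" %in% names(pts)) pts$is_tumor <- NA
  if (!"is_positive" %in% names(pts)) pts$is_positive <- NA
  pts <- pts[, c("x", "y", "confidence", "is_tumor", "is_positive")]
  write.csv(pts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pdl1tps-io
#' @export
read_points_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' Serialize / read a TPS result as JSON
#'
#' The JSON object records `slide_id`, the two counts, the TPS percentage,
#' the expression level, the coordinate convention, and the per-tile
#' breakdown.
#'
#' @param result A `tps_result`.
#' @param path File path.
#' @param slide_id Identifier stored in the JSON.
#' @export
write_tps_json <- function(result, path, slide_id = "slide") {
  stopifnot(inherits(result, "tps_result"))
  obj <- list(
    slide_id = slide_id,
    coordinate_convention = "0-based, half-open, x rightward, y downward",
    n_pt = result$n_pt, n_tt = result$n_tt,
    tps_percent = result$tps_percent,
    level = as.character(result$expression_level),
    tiles = result$tiles
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_tps_json
#' @export
read_tps_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read pipeline parameters from a YAML config
#'
#' Sections `membrane`, `nms`, `repel`, `scoring` override the corresponding
#' parameter-set defaults; missing sections keep defaults.
#'
#' @param path YAML file path.
#' @return Named list of parameter objects.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  list(
    membrane = do.call(membrane_params, cfg$membrane %||% list()),
    nms = do.call(nms_params, cfg$nms %||% list()),
    repel = do.call(repel_params, cfg$repel %||% list()),
    scoring = cfg$scoring %||% list(rho = 8, threshold = 0.5)
  )
}
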