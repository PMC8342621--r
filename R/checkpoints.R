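# Checkpointing: weights in a single RDS file with a JSON config sidecar, and
# reading back the emitted training directories.

#' Save / load a trained model
#'
#' Weights go to `path` (RDS); the architecture configuration is written to a
#' human-readable JSON sidecar `path.json` and is what `load_model()` uses to
#' rebuild the network before restoring weights.
#'
#' @param model A `seg_model` or `det_model`.
#' @param path Weights file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  kind <- if (inherits(model, "seg_model")) "seg" else "det"
  state <- lapply(model$params, function(p) p$value)
  saveRDS(list(kind = kind, state = state,
               nms_threshold = model$nms_threshold), path)
  jsonlite::write_json(c(list(kind = kind), unclass(model$config)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  kind <- cfg$kind
  cfg$kind <- NULL
  model <- if (kind == "seg") {
    build_res50_unet(do.call(seg_model_config, cfg[names(cfg) %in%
      names(formals(seg_model_config))]))
  } else {
    build_micronet(do.call(det_model_config, cfg[names(cfg) %in%
      names(formals(det_model_config))]))
  }
  for (i in seq_along(model$params)) model$params[[i]]$value <- blob$state[[i]]
  model$nms_threshold <- blob$nms_threshold
  model
}

#' Read an emitted training directory back into sample lists
#'
#' Reads the `seg/` (image + mask PNG pairs) or `det/` (image PNG + centre
#' CSV) halves of a directory written by [emit_training_sets()].
#'
#' @param dir Dataset root directory.
#' @param kind `"seg"` or `"det"`.
#' @return List of samples suitable for [train_segmentation()] /
#'   [train_nuclei_detector()].
#' @export
load_training_tiles <- function(dir, kind = c("seg", "det")) {
  kind <- match.arg(kind)
  if (kind == "seg") {
    imgs <- sort(list.files(file.path(dir, "seg/images"), full.names = TRUE))
    lapply(imgs, function(f) {
      list(image = read_rgb_png(f) / 255,
           mask = read_mask_png(file.path(dir, "seg/masks", basename(f))))
    })
  } else {
    imgs <- sort(list.files(file.path(dir, "det/images"), full.names = TRUE))
    lapply(imgs, function(f) {
      csv <- file.path(dir, "det/centers",
                       sub("\\.png$", ".csv", basename(f)))
      list(image = read_rgb_png(f) / 255, centers = read_points_csv(csv))
    })
  }
}
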