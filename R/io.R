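# File I/O: slides and masks as PNG (plus TIFF reading via EBImage),
# manifests and score tables as CSV, model checkpoints with JSON sidecars.

#' Read a slide image from disk
#'
#' @param path PNG or TIFF file.
#' @return H x W x 3 array in \[0,1\].
#' @export
read_slide <- function(path) {
  if (!file.exists(path)) stop("cannot read slide: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    a <- EBImage::readImage(path)
    # EBImage uses x,y order; transpose back to row = y
    aperm(as.array(a), c(2, 1, 3))
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write a slide image as PNG
#' @param img H x W x 3 array in \[0,1\], or a `synthetic_slide`.
#' @param path Output path.
#' @export
write_slide_png <- function(img, path) {
  if (inherits(img, "synthetic_slide")) img <- img$image
  png::writePNG(img, path)
  invisible(path)
}

#' Write a binary mask as single-channel PNG
#' @param mask Logical matrix or `tissue_mask`.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write tissue/hole contours as GeoJSON-style polygons
#' @param mask A `tissue_mask`.
#' @param path Output JSON path.
#' @export
write_contours_json <- function(mask, path) {
  poly <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  obj <- list(
    type = "FeatureCollection",
    downsample_factor = mask$downsample_factor,
    otsu_threshold = mask$otsu_threshold,
    features = c(
      lapply(mask$tissue_contours, function(m)
        list(type = "Feature", properties = list(kind = "tissue"),
             geometry = list(type = "Polygon", coordinates = list(poly(m))))),
      lapply(mask$hole_contours, function(m)
        list(type = "Feature", properties = list(kind = "hole"),
             geometry = list(type = "Polygon", coordinates = list(poly(m)))))
    ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save an anomaly model checkpoint with a JSON sidecar
#'
#' The checkpoint is an RDS file; `<path>.json` records the architecture
#' spec, training config and seed for provenance.
#'
#' @param model A `plaq_autoencoder` or `plaq_fanogan`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(class = class(model)[1],
                            spec = unclass(model$spec),
                            cfg = unclass(model$cfg)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an anomaly model checkpoint
#' @param path Checkpoint path written by [save_model()].
#' @return The model object.
#' @export
load_model <- function(path) readRDS(path)

#' Write per-patch anomaly scores as CSV
#' @param manifest Patch manifest.
#' @param scores Per-patch scores aligned with the manifest.
#' @param path Output CSV.
#' @export
write_scores_csv <- function(manifest, scores, path) {
  out <- manifest[, c("patient_id", "slide_id", "x0", "y0")]
  out$score <- scores
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
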