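# Sliding-window patch extraction from segmented tissue regions.  Patches
# are defined on the full-resolution (level-0) pixel grid; tissue coverage
# is evaluated area-weighted on the downsampled mask so the full-resolution
# mask never needs to be materialized.

#' Patch-grid parameters
#'
#' @param patch_px Patch side length in level-0 pixels (default 256).
#' @param stride_px Window stride (default 256, i.e. non-overlapping).
#' @param min_tissue_fraction Minimum fraction of a window covered by
#'   tissue for the window to be emitted (default 0.5).
#' @return A `patch_grid_params` object.
#' @export
patch_grid_params <- function(patch_px = 256L, stride_px = 256L,
                              min_tissue_fraction = 0.5) {
  if (patch_px < 32) stop("patch_px must be at least 32")
  if (stride_px < 1) stop("stride_px must be at least 1")
  if (min_tissue_fraction <= 0 || min_tissue_fraction > 1)
    stop("min_tissue_fraction must be in (0, 1]")
  structure(list(patch_px = as.integer(patch_px),
                 stride_px = as.integer(stride_px),
                 min_tissue_fraction = min_tissue_fraction),
            class = "patch_grid_params")
}

# Area-weighted tissue fraction of the level-0 window [x0, x0+size) x
# [y0, y0+size) on a downsampled mask (each mask cell covers ds^2 pixels).
window_tissue_fraction <- function(mask, ds, x0, y0, size) {
  # overlap of the window with mask cell columns/rows, in level-0 pixels
  cx0 <- x0 / ds; cx1 <- (x0 + size) / ds
  cy0 <- y0 / ds; cy1 <- (y0 + size) / ds
  js <- seq(floor(cx0), ceiling(cx1) - 1)         # 0-based cell cols
  is <- seq(floor(cy0), ceiling(cy1) - 1)         # 0-based cell rows
  wj <- pmin(js + 1, cx1) - pmax(js, cx0)         # fractional col overlap
  wi <- pmin(is + 1, cy1) - pmax(is, cy0)
  js_in <- js + 1; is_in <- is + 1
  keep_j <- js_in >= 1 & js_in <= ncol(mask)
  keep_i <- is_in >= 1 & is_in <= nrow(mask)
  sub <- matrix(0, length(is), length(js))
  sub[keep_i, keep_j] <- mask[is_in[keep_i], js_in[keep_j], drop = FALSE] + 0
  as.numeric(wi %*% sub %*% wj) / (size / ds)^2
}

#' Extract the tissue patch grid from a segmentation mask
#'
#' Tiles the slide with `patch_px` windows at `stride_px` starting from the
#' origin, drops windows extending past the slide edge, and emits a window
#' iff its area-weighted tissue fraction on the downsampled mask reaches
#' `min_tissue_fraction`.  Coordinates are 0-based level-0 pixels of the
#' window's top-left corner; output is sorted by (y0, x0).
#'
#' @param mask A `tissue_mask` from [segment_tissue()].
#' @param slide_dims Level-0 slide dimensions `c(width, height)` in pixels.
#' @param params A [patch_grid_params()].
#' @param patient_id,slide_id Identifiers recorded in the manifest.
#' @return Data frame (patch manifest) with columns `patient_id`,
#'   `slide_id`, `x0`, `y0`, `size_px`, `tissue_fraction`, `label`.
#' @export
extract_patch_grid <- function(mask, slide_dims, params = patch_grid_params(),
                               patient_id = "NA", slide_id = "NA") {
  stopifnot(inherits(mask, "tissue_mask"))
  W <- slide_dims[1]; H <- slide_dims[2]
  ds <- mask$downsample_factor
  p <- params$patch_px; st <- params$stride_px
  xs <- seq(0L, W - p, by = st)
  ys <- seq(0L, H - p, by = st)
  if (W < p || H < p || !any(mask$mask)) {
    return(data.frame(patient_id = character(0), slide_id = character(0),
                      x0 = integer(0), y0 = integer(0), size_px = integer(0),
                      tissue_fraction = numeric(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  recs <- list()
  for (y0 in ys) for (x0 in xs) {
    tf <- window_tissue_fraction(mask$mask, ds, x0, y0, p)
    if (tf >= params$min_tissue_fraction)
      recs[[length(recs) + 1L]] <- c(x0, y0, tf)
  }
  if (length(recs) == 0) {
    return(data.frame(patient_id = character(0), slide_id = character(0),
                      x0 = integer(0), y0 = integer(0), size_px = integer(0),
                      tissue_fraction = numeric(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, recs)
  out <- data.frame(patient_id = patient_id, slide_id = slide_id,
                    x0 = as.integer(m[, 1]), y0 = as.integer(m[, 2]),
                    size_px = p, tissue_fraction = m[, 3],
                    label = "unknown", stringsAsFactors = FALSE)
  out[order(out$y0, out$x0), , drop = FALSE]
}

#' Read the pixel content of one patch from a slide
#'
#' @param slide Slide input accepted by [segment_tissue()].
#' @param record One row of a patch manifest (list or single-row data
#'   frame with `x0`, `y0`, `size_px`).
#' @return `size_px` x `size_px` x 3 array in \[0,1\].
#' @export
read_patch <- function(slide, record) {
  img <- as_slide_array(slide)
  x0 <- record$x0; y0 <- record$y0; p <- record$size_px
  H <- dim(img)[1]; W <- dim(img)[2]
  if (x0 < 0 || y0 < 0 || x0 + p > W || y0 + p > H)
    stop("patch coordinates out of slide bounds")
  img[y0 + seq_len(p), x0 + seq_len(p), , drop = FALSE]
}

#' Read all patches of a manifest into a patch-bank array
#'
#' @param slide Slide input.
#' @param manifest Patch manifest from [extract_patch_grid()].
#' @return `patch_bank` with `pixels` (p x p x 3 x n) and the manifest.
#' @export
read_patches <- function(slide, manifest) {
  img <- as_slide_array(slide)
  n <- nrow(manifest)
  p <- if (n > 0) manifest$size_px[1] else 0L
  pixels <- array(0, c(p, p, 3, max(n, 0L)))
  for (i in seq_len(n))
    pixels[, , , i] <- read_patch(img, manifest[i, ])
  structure(list(pixels = pixels, label = manifest$label, patch_px = p,
                 manifest = manifest),
            class = "patch_bank")
}
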