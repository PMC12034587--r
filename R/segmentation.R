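# Tissue/hole segmentation of slide images: downsample, HSV saturation,
# median filter, Otsu binarization, morphological closing, and contour
# extraction with a tissue/hole hierarchy.  Standard image operations go
# through EBImage; the Otsu threshold search itself is implemented on the
# 256-bin histogram with an explicit smallest-index tie rule.

#' Segmentation parameters
#'
#' @param downsample_factor Integer downsample applied before segmentation
#'   (default 32, the working resolution for whole-slide inputs).
#' @param median_kernel_px Odd median-filter window side at the downsampled
#'   level (default 7).
#' @param closing_kernel_px Odd morphological-closing kernel side (default 5).
#' @param min_tissue_area_px Minimum connected tissue-component area, in
#'   downsampled pixels (default 512 at downsample 32).
#' @param min_hole_area_px Minimum hole area retained as a hole; smaller
#'   holes are filled (default 256).
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(downsample_factor = 32L, median_kernel_px = 7L,
                                closing_kernel_px = 5L,
                                min_tissue_area_px = 512L,
                                min_hole_area_px = 256L) {
  if (downsample_factor < 1) stop("downsample_factor must be >= 1")
  if (median_kernel_px < 1 || median_kernel_px %% 2 == 0)
    stop("median_kernel_px must be odd and >= 1")
  if (closing_kernel_px < 1 || closing_kernel_px %% 2 == 0)
    stop("closing_kernel_px must be odd and >= 1")
  if (min_tissue_area_px < 0 || min_hole_area_px < 0)
    stop("area minima must be nonnegative")
  structure(list(downsample_factor = as.integer(downsample_factor),
                 median_kernel_px = as.integer(median_kernel_px),
                 closing_kernel_px = as.integer(closing_kernel_px),
                 min_tissue_area_px = as.integer(min_tissue_area_px),
                 min_hole_area_px = as.integer(min_hole_area_px)),
            class = "segmentation_params")
}

#' Otsu threshold of a 256-bin intensity histogram
#'
#' Returns the bin index `t` in 0..255 that maximizes the between-class
#' variance of the split into bins `0..t` versus `t+1..255`.  Ties are
#' broken toward the smallest index.  The degenerate single-populated-bin
#' histogram returns that bin's index.
#'
#' @param histogram Nonnegative integer counts of length 256.
#' @return Integer threshold in 0..255.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256) stop("histogram must have 256 bins")
  if (any(histogram < 0)) stop("histogram counts must be nonnegative")
  total <- sum(histogram)
  if (total == 0) stop("histogram is empty")
  nz <- which(histogram > 0)
  if (length(nz) == 1L) return(nz - 1L)
  levels <- 0:255
  w0 <- cumsum(histogram)
  m0 <- cumsum(histogram * levels)
  mu_total <- m0[256] / total
  w0n <- w0 / total
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  w1n <- 1 - w0n
  mu1 <- ifelse(w1n > 0, (m0[256] - m0) / (total - w0), 0)
  bcv <- w0n * w1n * (mu0 - mu1)^2
  bcv[!is.finite(bcv)] <- 0
  as.integer(which.max(bcv) - 1L)  # which.max takes the first maximum
}

# Block-mean downsample of a matrix or H x W x C array by integer factor;
# trailing rows/cols that do not fill a block are dropped.
#' Downsample an image by integer block averaging
#' @param img Matrix or H x W x C array.
#' @param factor Integer downsample factor.
#' @return Downsampled matrix/array.
#' @export
downsample_image <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  ds_mat <- function(m) {
    h <- nrow(m) %/% factor * factor
    w <- ncol(m) %/% factor * factor
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    # average factor x factor blocks
    m <- matrix(colMeans(matrix(m, factor)), h %/% factor, w)
    t(matrix(colMeans(matrix(t(m), factor)), w %/% factor, h %/% factor))
  }
  if (length(dim(img)) == 2) return(ds_mat(img))
  out <- NULL
  for (ch in seq_len(dim(img)[3])) {
    d <- ds_mat(img[, , ch])
    if (is.null(out)) out <- array(0, c(dim(d), dim(img)[3]))
    out[, , ch] <- d
  }
  out
}

# HSV saturation channel of an RGB [0,1] array: S = (max - min) / max.
rgb_saturation <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  matrix(s, dim(img)[1], dim(img)[2])
}

# Oriented contour of a single-component binary matrix as an (x, y) matrix
# of 0-based pixel coordinates (x = column, y = row).
.component_contour <- function(mask01) {
  oc <- EBImage::ocontour(mask01)
  if (length(oc) == 0) return(matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("x", "y"))))
  m <- oc[[1]]
  # EBImage coordinates follow array dims: first column = dim1 = row.
  out <- cbind(x = m[, 2], y = m[, 1])
  out
}

#' Segment tissue and holes from a slide image
#'
#' Fixed pipeline: integer downsample, RGB to HSV saturation, median
#' filter, Otsu binarization of the 256-bin saturation histogram,
#' morphological closing, then connected-component analysis: filled
#' components above the tissue area minimum become tissue regions, and
#' enclosed background regions above the hole area minimum become holes.
#' The returned mask is true exactly on tissue pixels outside all retained
#' holes; holes below the area minimum are filled.
#'
#' @param slide A `synthetic_slide`, an H x W x 3 array in \[0,1\], or a
#'   path to a PNG/TIFF image.
#' @param params A [segmentation_params()].
#' @return A `tissue_mask`: list with `mask` (logical h x w at the
#'   downsampled resolution), `downsample_factor`, `tissue_contours` and
#'   `hole_contours` (lists of (x, y) polygon matrices, 0-based downsampled
#'   coordinates), and `otsu_threshold` (integer in 0..255).
#' @export
segment_tissue <- function(slide, params = segmentation_params()) {
  img <- as_slide_array(slide)
  ds <- downsample_image(img, params$downsample_factor)
  s <- rgb_saturation(ds)
  if (nrow(s) < params$median_kernel_px || ncol(s) < params$median_kernel_px)
    stop("downsampled image smaller than the median kernel")
  if (params$median_kernel_px > 1) {
    r <- (params$median_kernel_px - 1L) %/% 2L
    s <- EBImage::medianFilter(s, r)
    s <- matrix(as.numeric(s), nrow(s), ncol(s))
  }
  counts <- tabulate(pmin(255L, pmax(0L, as.integer(floor(s * 255)))) + 1L,
                     nbins = 256L)
  thr <- otsu_threshold(counts)
  bin <- matrix(as.numeric(floor(s * 255) > thr), nrow(s), ncol(s))
  if (params$closing_kernel_px > 1) {
    kern <- EBImage::makeBrush(params$closing_kernel_px, shape = "disc")
    bin <- EBImage::closing(bin, kern)
    bin <- matrix(as.numeric(bin), nrow(bin), ncol(bin))
  }

  filled <- EBImage::fillHull(bin)
  filled <- matrix(as.numeric(filled) > 0.5, nrow(bin), ncol(bin))
  lab <- EBImage::bwlabel(matrix(as.numeric(filled), nrow(bin)))
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_tissue_area_px)

  tissue_contours <- list()
  hole_contours <- list()
  mask <- matrix(FALSE, nrow(bin), ncol(bin))
  holes_all <- filled & !(bin > 0.5)
  for (k in keep) {
    comp <- lab == k
    mask <- mask | comp
    tissue_contours[[length(tissue_contours) + 1L]] <-
      .component_contour(matrix(as.numeric(comp), nrow(bin)))
    # holes inside this component
    ch <- holes_all & comp
    if (any(ch)) {
      hl <- EBImage::bwlabel(matrix(as.numeric(ch), nrow(bin)))
      hl <- matrix(as.integer(hl), nrow(bin), ncol(bin))
      ha <- tabulate(hl[hl > 0])
      for (hk in which(ha >= params$min_hole_area_px)) {
        hm <- hl == hk
        mask[hm] <- FALSE
        hole_contours[[length(hole_contours) + 1L]] <-
          .component_contour(matrix(as.numeric(hm), nrow(bin)))
      }
    }
  }
  structure(list(mask = mask,
                 downsample_factor = params$downsample_factor,
                 tissue_contours = tissue_contours,
                 hole_contours = hole_contours,
                 otsu_threshold = thr),
            class = "tissue_mask")
}

# Coerce the accepted slide inputs to an H x W x 3 array in [0,1].
as_slide_array <- function(slide) {
  if (inherits(slide, "synthetic_slide")) return(slide$image)
  if (is.character(slide)) return(read_slide(slide))
  if (is.array(slide) && length(dim(slide)) == 3 && dim(slide)[3] >= 3)
    return(slide[, , 1:3, drop = FALSE])
  stop("cannot interpret slide input")
}
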