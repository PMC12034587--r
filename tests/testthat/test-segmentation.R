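test_that("Otsu threshold handles the two-spike and degenerate histograms", {
  h <- integer(256)
  h[50 + 1] <- 100; h[200 + 1] <- 100
  # any split in [50, 200) separates the spikes; smallest index wins
  expect_identical(otsu_threshold(h), 50L)
  expect_identical(otsu_threshold(h), otsu_bruteforce(h))

  h1 <- integer(256); h1[123 + 1] <- 42
  expect_identical(otsu_threshold(h1), 123L)

  expect_error(otsu_threshold(integer(256)), "empty")
  expect_error(otsu_threshold(integer(10)), "256")
})

test_that("Otsu threshold separates a two-Gaussian mixture at the scan optimum", {
  set.seed(99)
  x <- c(rnorm(5000, 60, 10), rnorm(5000, 190, 10))
  h <- tabulate(pmin(255, pmax(0, round(x))) + 1L, nbins = 256L)
  t <- otsu_threshold(h)
  expect_identical(t, otsu_bruteforce(h))
  expect_gt(t, 60); expect_lt(t, 190)
})

test_that("a saturated disc on white background segments at high IoU", {
  cfg <- slide_gen_config(width_px = 1024L, height_px = 1024L, seed = 3L,
                          blob_centers = matrix(c(512, 512), 1),
                          blob_radii = 200)
  s <- generate_slide(cfg)
  m <- segment_tissue(s, segmentation_params(downsample_factor = 8L))
  truth <- downsample_image(s$tissue_truth * 1.0, 8L) > 0.5
  iou <- sum(m$mask & truth) / sum(m$mask | truth)
  expect_gte(iou, 0.90)
  expect_length(m$tissue_contours, 1L)
  expect_true(m$otsu_threshold >= 0 && m$otsu_threshold <= 255)
})

test_that("a blank slide yields an empty mask and no contours", {
  blank <- array(245 / 255, c(1024, 1024, 3))
  m <- segment_tissue(blank, segmentation_params(downsample_factor = 8L))
  expect_false(any(m$mask))
  expect_length(m$tissue_contours, 0L)
})

test_that("a background-colored hole inside tissue is extracted as a hole contour", {
  cfg <- slide_gen_config(width_px = 1024L, height_px = 1024L, seed = 4L,
                          blob_centers = matrix(c(512, 512), 1),
                          blob_radii = 300,
                          hole_centers = matrix(c(512, 512), 1),
                          hole_radii = 80)
  s <- generate_slide(cfg)
  m <- segment_tissue(s, segmentation_params(downsample_factor = 8L,
                                             min_hole_area_px = 20L))
  expect_length(m$tissue_contours, 1L)
  expect_length(m$hole_contours, 1L)
  expect_false(m$mask[64, 64])  # hole center is not tissue
  expect_true(m$mask[64, 30])   # ring is tissue
})

test_that("segmentation is idempotent on an already-binarized image", {
  cfg <- slide_gen_config(width_px = 1024L, height_px = 1024L, seed = 6L)
  s <- generate_slide(cfg)
  p <- segmentation_params(downsample_factor = 8L)
  m1 <- segment_tissue(s, p)
  # repaint: pure tissue color on mask, pure white elsewhere, at mask scale
  pal <- plaq_palettes()
  h <- nrow(m1$mask); w <- ncol(m1$mask)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- ifelse(m1$mask, pal$tissue[ch] / 255, 1)
  m2 <- segment_tissue(img, segmentation_params(
    downsample_factor = 1L, median_kernel_px = 1L, closing_kernel_px = 1L,
    min_tissue_area_px = p$min_tissue_area_px,
    min_hole_area_px = p$min_hole_area_px))
  expect_identical(m2$mask, m1$mask)
  expect_length(m2$tissue_contours, length(m1$tissue_contours))
})

test_that("raising the tissue area minimum never increases contour count", {
  cfg <- slide_gen_config(width_px = 1024L, height_px = 1024L,
                          tissue_blob_count = 3L, seed = 14L)
  s <- generate_slide(cfg)
  counts <- sapply(c(0L, 100L, 1000L, 5000L), function(a) {
    m <- segment_tissue(s, segmentation_params(downsample_factor = 8L,
                                               min_tissue_area_px = a))
    length(m$tissue_contours)
  })
  expect_true(all(diff(counts) <= 0))
})
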