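mk_mask <- function(mask, ds) {
  structure(list(mask = mask, downsample_factor = ds,
                 tissue_contours = list(), hole_contours = list(),
                 otsu_threshold = 0L),
            class = "tissue_mask")
}

test_that("an all-tissue slide tiles into the full non-overlapping grid", {
  m <- mk_mask(matrix(TRUE, 32, 32), 32L)
  g <- extract_patch_grid(m, c(1024L, 1024L), patch_grid_params(256L, 256L, 0.5))
  expect_equal(nrow(g), 16L)
  expect_setequal(unique(g$x0), c(0L, 256L, 512L, 768L))
  expect_setequal(unique(g$y0), c(0L, 256L, 512L, 768L))
  # sorted by (y0, x0)
  expect_identical(order(g$y0, g$x0), seq_len(nrow(g)))
  # non-overlap at stride == patch size
  key <- paste(g$x0 %/% 256, g$y0 %/% 256)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("an empty mask yields an empty manifest, not an error", {
  m <- mk_mask(matrix(FALSE, 32, 32), 32L)
  g <- extract_patch_grid(m, c(1024L, 1024L))
  expect_equal(nrow(g), 0L)
})

test_that("emitted windows match exhaustive enumeration on random masks", {
  set.seed(123)
  for (rep in 1:20) {
    mask <- matrix(runif(16 * 16) > 0.55, 16, 16)
    m <- mk_mask(mask, 16L)
    p <- 40L; st <- 24L; mf <- 0.5
    g <- extract_patch_grid(m, c(256L, 256L), patch_grid_params(p, st, mf))
    oracle <- patch_grid_bruteforce(mask, 16L, 256L, 256L, p, st, mf)
    n_oracle <- if (is.null(oracle)) 0L else nrow(oracle)
    expect_equal(nrow(g), n_oracle)
    if (n_oracle > 0) {
      o <- oracle[order(oracle[, 2], oracle[, 1]), , drop = FALSE]
      expect_equal(g$x0, as.integer(o[, 1]))
      expect_equal(g$y0, as.integer(o[, 2]))
      expect_equal(g$tissue_fraction, o[, 3], tolerance = 1e-12)
    }
    # coverage bound
    expect_lte(nrow(g), floor(256 / st) * floor(256 / st))
  }
})

test_that("a half-tissue slide emits exactly the windows over the tissue half", {
  mask <- cbind(matrix(TRUE, 32, 16), matrix(FALSE, 32, 16))
  m <- mk_mask(mask, 32L)
  g <- extract_patch_grid(m, c(1024L, 1024L), patch_grid_params(256L, 256L, 0.5))
  oracle <- patch_grid_bruteforce(mask, 32L, 1024L, 1024L, 256L, 256L, 0.5)
  expect_equal(nrow(g), nrow(oracle))
  expect_true(all(g$x0 <= 256L))
})

test_that("patch reads are reproducible, respect bounds, and hit lesions", {
  cfg <- slide_gen_config(width_px = 1024L, height_px = 1024L, seed = 9L,
                          blob_centers = matrix(c(512, 512), 1),
                          blob_radii = 300,
                          lesion_centers = matrix(c(512, 512), 1),
                          lesion_radii = 60)
  s <- generate_slide(cfg)
  rec <- list(x0 = 480L, y0 = 480L, size_px = 64L)
  p1 <- read_patch(s, rec)
  p2 <- read_patch(s, rec)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(64L, 64L, 3L))
  # lesion overlap in the ground truth crop
  crop <- s$anomaly_truth[rec$y0 + 1:64, rec$x0 + 1:64]
  expect_gt(sum(crop), 0)

  # constant background region
  corner <- read_patch(s, list(x0 = 0L, y0 = 0L, size_px = 32L))
  expect_lt(diff(range(corner)), 0.1)  # near-constant background

  expect_error(read_patch(s, list(x0 = 1000L, y0 = 0L, size_px = 64L)),
               "bounds")
})

test_that("mask cells indexed by level-0 coordinates drive the tissue fraction", {
  mask <- matrix(FALSE, 8, 8); mask[1:4, 1:4] <- TRUE
  # window exactly over the true quadrant
  expect_equal(plaqrisk:::window_tissue_fraction(mask, 32, 0, 0, 128), 1)
  # window exactly over the false quadrant
  expect_equal(plaqrisk:::window_tissue_fraction(mask, 32, 128, 128, 128), 0)
  # straddling window: half tissue
  expect_equal(plaqrisk:::window_tissue_fraction(mask, 32, 64, 0, 128), 0.5)
})
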