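# Seeded synthetic slides, patch banks and clinical tables.  These emulate
# the appearance of H&E-stained carotid plaque sections well enough to
# exercise every downstream stage (segmentation, patching, anomaly scoring,
# risk aggregation, classification) with exact ground truth.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators do not perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Color palettes used by the synthetic slide generator
#'
#' Normal tissue is rendered around a pink H&E hue on a near-white
#' background; the three anomalous textures mimic plaque hemorrhage
#' (dark red clots), lymphocytic infiltration (dense small dark dots) and
#' hemosiderin deposition (brown granules).  All values are 8-bit RGB.
#'
#' @return Named list of RGB triplets and texture coverage constants.
#' @export
plaq_palettes <- function() {
  list(
    background    = c(245, 245, 245),
    tissue        = c(230, 160, 190),
    nucleus       = c(100, 60, 140),
    hemorrhage    = c(140, 30, 40),
    infiltrate    = c(60, 40, 120),
    deposit       = c(120, 70, 30),
    deposit_dark  = c(90, 55, 20),
    # texture constants (fractions)
    speckle_density    = 0.002,  # nuclei dots per tissue pixel
    infiltrate_density = 0.06,   # dot centers per lesion pixel
    deposit_blend      = 0.5,    # tissue/brown blend inside deposit lesions
    lesion_patch_radius = 0.35   # lesion disc radius as fraction of patch size
  )
}

#' Configuration for the synthetic slide generator
#'
#' @param width_px,height_px Slide dimensions in pixels (at least 512).
#' @param background_rgb Background color, 8-bit RGB triplet.
#' @param tissue_blob_count Number of tissue blobs.
#' @param hole_count Number of background-colored holes punched into tissue.
#' @param anomaly_lesion_count Number of anomalous lesions placed in tissue.
#' @param anomaly_texture One of `"hemorrhage_like"`, `"infiltrate_like"`,
#'   `"deposit_like"`.
#' @param noise_sd Gaussian pixel noise standard deviation in 8-bit units.
#' @param seed Integer RNG seed; generation is bit-reproducible.
#' @param blob_centers,blob_radii Optional explicit blob geometry
#'   (`blob_centers` is an n x 2 matrix of (x, y) centers); when supplied,
#'   blobs are exact circles, which is convenient for closed-form checks.
#' @param hole_centers,hole_radii,lesion_centers,lesion_radii Optional
#'   explicit hole/lesion geometry, same conventions.
#' @return A `slide_gen_config` object.
#' @export
slide_gen_config <- function(width_px = 1024L, height_px = 1024L,
                             background_rgb = c(245, 245, 245),
                             tissue_blob_count = 2L, hole_count = 0L,
                             anomaly_lesion_count = 0L,
                             anomaly_texture = c("hemorrhage_like",
                                                 "infiltrate_like",
                                                 "deposit_like"),
                             noise_sd = 6, seed = 1L,
                             blob_centers = NULL, blob_radii = NULL,
                             hole_centers = NULL, hole_radii = NULL,
                             lesion_centers = NULL, lesion_radii = NULL) {
  anomaly_texture <- match.arg(anomaly_texture)
  if (width_px < 512 || height_px < 512)
    stop("slide dimensions must be at least 512 px")
  if (tissue_blob_count < 0 || hole_count < 0 || anomaly_lesion_count < 0)
    stop("counts must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(background_rgb) != 3 || any(background_rgb < 0 | background_rgb > 255))
    stop("background_rgb must be an 8-bit RGB triplet")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 background_rgb = background_rgb,
                 tissue_blob_count = as.integer(tissue_blob_count),
                 hole_count = as.integer(hole_count),
                 anomaly_lesion_count = as.integer(anomaly_lesion_count),
                 anomaly_texture = anomaly_texture,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 blob_centers = blob_centers, blob_radii = blob_radii,
                 hole_centers = hole_centers, hole_radii = hole_radii,
                 lesion_centers = lesion_centers, lesion_radii = lesion_radii),
            class = "slide_gen_config")
}

# Logical h x w ellipse mask; exact circle when rx == ry.
.ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

# Add dark round dots at `centers` (matrix of (row, col)) with radius 1-2 px.
.stamp_dots <- function(img, centers, rgb01, radius = 1L) {
  if (nrow(centers) == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  for (k in seq_len(nrow(offs))) {
    ys <- centers[, 1] + offs$dy[k]
    xs <- centers[, 2] + offs$dx[k]
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    if (!any(ok)) next
    idx <- cbind(ys[ok], xs[ok])
    for (ch in 1:3) img[cbind(idx, ch)] <- rgb01[ch]
  }
  img
}

# Render normal tissue texture into the pixels selected by `mask` (or the
# whole canvas when mask is NULL): pink base + noise + sparse nuclei dots.
.render_tissue <- function(img, mask, noise_sd) {
  pal <- plaq_palettes()
  h <- dim(img)[1]; w <- dim(img)[2]
  n <- sum(mask)
  if (n == 0) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- pal$tissue[ch] / 255 +
      stats::rnorm(n, sd = noise_sd / 255)
    img[, , ch] <- plane
  }
  # nuclei speckle
  k <- round(pal$speckle_density * n)
  if (k > 0) {
    idx <- which(mask)
    pick <- idx[sample.int(length(idx), min(k, length(idx)))]
    centers <- cbind((pick - 1) %% h + 1, (pick - 1) %/% h + 1)
    img <- .stamp_dots(img, centers, pal$nucleus / 255, radius = 1L)
  }
  img
}

# Paint one anomalous texture into lesion pixels.
.render_lesion <- function(img, mask, texture, noise_sd) {
  pal <- plaq_palettes()
  h <- dim(img)[1]
  n <- sum(mask)
  if (n == 0) return(img)
  if (texture == "hemorrhage_like") {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- pal$hemorrhage[ch] / 255 +
        stats::rnorm(n, sd = 2 * noise_sd / 255)
      img[, , ch] <- plane
    }
  } else if (texture == "infiltrate_like") {
    k <- round(pal$infiltrate_density * n)
    idx <- which(mask)
    pick <- idx[sample.int(length(idx), min(k, length(idx)), replace = FALSE)]
    centers <- cbind((pick - 1) %% h + 1, (pick - 1) %/% h + 1)
    img <- .stamp_dots(img, centers, pal$infiltrate / 255, radius = 1L)
  } else { # deposit_like
    b <- pal$deposit_blend
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- (1 - b) * plane[mask] + b * pal$deposit[ch] / 255 +
        stats::rnorm(n, sd = noise_sd / 255)
      img[, , ch] <- plane
    }
    k <- round(0.02 * n)
    if (k > 0) {
      idx <- which(mask)
      pick <- idx[sample.int(length(idx), min(k, length(idx)))]
      centers <- cbind((pick - 1) %% h + 1, (pick - 1) %/% h + 1)
      img <- .stamp_dots(img, centers, pal$deposit_dark / 255, radius = 1L)
    }
  }
  img
}

.quantize8 <- function(img) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  round(img * 255) / 255
}

#' Generate a synthetic H&E-like slide with ground-truth masks
#'
#' Renders pink/purple tissue blobs on a bright background, optionally with
#' background-colored holes and anomalous lesions of a configured texture.
#' The returned ground truth makes every downstream stage testable: the
#' tissue mask excludes holes, and every anomalous pixel is a tissue pixel.
#'
#' @param config A [slide_gen_config()].
#' @return A `synthetic_slide`: list with `image` (H x W x 3 array in
#'   \[0,1\], quantized to 8-bit levels), `tissue_truth` and `anomaly_truth`
#'   (logical H x W matrices) and `seed`.
#' @export
generate_slide <- function(config) {
  stopifnot(inherits(config, "slide_gen_config"))
  with_seed(config$seed, {
    h <- config$height_px; w <- config$width_px
    mind <- min(h, w)
    img <- array(0, c(h, w, 3))
    for (ch in 1:3)
      img[, , ch] <- config$background_rgb[ch] / 255 +
        stats::rnorm(h * w, sd = config$noise_sd / 255 / 2)

    # --- tissue blobs ---
    tissue <- matrix(FALSE, h, w)
    if (!is.null(config$blob_centers)) {
      centers <- config$blob_centers
      radii <- config$blob_radii
      if (is.null(radii) || nrow(centers) != length(radii))
        stop("blob_centers and blob_radii must match")
      for (i in seq_len(nrow(centers)))
        tissue <- tissue | .ellipse_mask(h, w, centers[i, 2], centers[i, 1],
                                         radii[i], radii[i])
    } else if (config$tissue_blob_count > 0) {
      margin <- 8
      for (i in seq_len(config$tissue_blob_count)) {
        r <- stats::runif(1, 0.12, 0.22) * mind
        ar <- stats::runif(1, 0.6, 1)
        ry <- r; rx <- r * ar
        if (2 * max(rx, ry) + 2 * margin > mind)
          stop("slide dimensions too small to place requested blobs")
        cy <- stats::runif(1, ry + margin, h - ry - margin)
        cx <- stats::runif(1, rx + margin, w - rx - margin)
        tissue <- tissue | .ellipse_mask(h, w, cy, cx, ry, rx)
      }
    }
    img <- .render_tissue(img, tissue, config$noise_sd)

    # --- holes (background-colored, removed from tissue truth) ---
    holes <- matrix(FALSE, h, w)
    if (!is.null(config$hole_centers)) {
      centers <- config$hole_centers; radii <- config$hole_radii
      for (i in seq_len(nrow(centers)))
        holes <- holes | .ellipse_mask(h, w, centers[i, 2], centers[i, 1],
                                       radii[i], radii[i])
    } else if (config$hole_count > 0 && any(tissue)) {
      idx <- which(tissue)
      for (i in seq_len(config$hole_count)) {
        p <- idx[sample.int(length(idx), 1)]
        cy <- (p - 1) %% h + 1; cx <- (p - 1) %/% h + 1
        r <- stats::runif(1, 0.025, 0.05) * mind
        holes <- holes | .ellipse_mask(h, w, cy, cx, r, r)
      }
    }
    holes <- holes & tissue
    if (any(holes)) {
      n <- sum(holes)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[holes] <- config$background_rgb[ch] / 255 +
          stats::rnorm(n, sd = config$noise_sd / 255 / 2)
        img[, , ch] <- plane
      }
      tissue <- tissue & !holes
    }

    # --- anomalous lesions ---
    anomaly <- matrix(FALSE, h, w)
    if (!is.null(config$lesion_centers)) {
      centers <- config$lesion_centers; radii <- config$lesion_radii
      for (i in seq_len(nrow(centers))) {
        m <- .ellipse_mask(h, w, centers[i, 2], centers[i, 1],
                           radii[i], radii[i]) & tissue
        img <- .render_lesion(img, m, config$anomaly_texture, config$noise_sd)
        anomaly <- anomaly | m
      }
    } else if (config$anomaly_lesion_count > 0 && any(tissue)) {
      idx <- which(tissue)
      for (i in seq_len(config$anomaly_lesion_count)) {
        p <- idx[sample.int(length(idx), 1)]
        cy <- (p - 1) %% h + 1; cx <- (p - 1) %/% h + 1
        r <- stats::runif(1, 0.05, 0.09) * mind
        m <- .ellipse_mask(h, w, cy, cx, r, r) & tissue
        img <- .render_lesion(img, m, config$anomaly_texture, config$noise_sd)
        anomaly <- anomaly | m
      }
    }

    structure(list(image = .quantize8(img), tissue_truth = tissue,
                   anomaly_truth = anomaly, seed = config$seed),
              class = "synthetic_slide")
  })
}

#' Expected mean-intensity contrast between anomalous and normal patches
#'
#' Closed-form prediction, from the generator palette and coverage
#' constants, of how much darker (in mean \[0,1\] intensity over all pixels
#' and channels) an anomalous patch is than a normal patch.
#'
#' @param texture Anomaly texture name.
#' @return Expected positive difference normal minus anomalous mean.
#' @export
expected_bank_contrast <- function(texture = c("hemorrhage_like",
                                               "infiltrate_like",
                                               "deposit_like")) {
  texture <- match.arg(texture)
  pal <- plaq_palettes()
  area <- pi * pal$lesion_patch_radius^2
  tis <- mean(pal$tissue) / 255
  lesion_mean <- switch(texture,
    hemorrhage_like = mean(pal$hemorrhage) / 255,
    # dots of ~5 px at the configured center density
    infiltrate_like = {
      cov <- min(1, 5 * pal$infiltrate_density)
      (1 - cov) * tis + cov * mean(pal$infiltrate) / 255
    },
    deposit_like = (1 - pal$deposit_blend) * tis +
      pal$deposit_blend * mean(pal$deposit) / 255)
  area * (tis - lesion_mean)
}

#' Generate a labelled bank of normal and anomalous texture patches
#'
#' Normal patches contain pure tissue texture; anomalous patches carry a
#' centered lesion disc of the configured texture.  Used as training and
#' evaluation fixtures for the anomaly models.
#'
#' @param config A [slide_gen_config()] (texture, noise and seed are used).
#' @param n_normal,n_anomalous Patch counts.
#' @param patch_px Patch side in pixels (at least 32).
#' @return A `patch_bank`: list with `pixels` (patch_px x patch_px x 3 x n
#'   array in \[0,1\]), `label` (character, `"normal"`/`"anomalous"`) and
#'   `patch_px`.
#' @export
generate_patch_bank <- function(config, n_normal, n_anomalous, patch_px = 64L) {
  stopifnot(inherits(config, "slide_gen_config"))
  if (patch_px < 32) stop("patch_px must be at least 32")
  n <- n_normal + n_anomalous
  with_seed(config$seed, {
    p <- as.integer(patch_px)
    pal <- plaq_palettes()
    pixels <- array(0, c(p, p, 3, n))
    label <- c(rep("normal", n_normal), rep("anomalous", n_anomalous))
    lesion <- .ellipse_mask(p, p, (p + 1) / 2, (p + 1) / 2,
                            pal$lesion_patch_radius * p,
                            pal$lesion_patch_radius * p)
    for (i in seq_len(n)) {
      img <- array(0, c(p, p, 3))
      img <- .render_tissue(img, matrix(TRUE, p, p), config$noise_sd)
      if (label[i] == "anomalous")
        img <- .render_lesion(img, lesion, config$anomaly_texture,
                              config$noise_sd)
      pixels[, , , i] <- .quantize8(img)
    }
    structure(list(pixels = pixels, label = label, patch_px = p),
              class = "patch_bank")
  })
}

# Flatten a patch bank (or a p x p x 3 x n array) into the (features x n)
# matrix layout consumed by the network engine.
bank_matrix <- function(bank) {
  px <- if (inherits(bank, "patch_bank")) bank$pixels else bank
  d <- dim(px)
  matrix(px, d[1] * d[2] * d[3], d[4])
}

# ---- clinical tables --------------------------------------------------------

#' Clinical feature schema (18 variables)
#'
#' The fixed schema of per-patient clinical variables: demographics and
#' imaging scores (age, sex, vessel stenosis rate, NIHSS, MPRAGE grade,
#' smoking history), comorbidities (hypertension, diabetes, dyslipidemia,
#' arteriosclerosis obliterans, coronary artery disease) and medications
#' (aspirin, ticlopidine, clopidogrel, cilostazol, warfarin,
#' heparin/argatroban, statins).  Default class-conditional distribution
#' parameters reflect a CEA cohort of 120 event-free and 21 event patients.
#'
#' @return Data frame with columns `name`, `type` and class-conditional
#'   parameters (`mean`/`sd` for continuous, prevalence `p` for binary).
#' @export
clinical_schema <- function() {
  data.frame(
    name = c("age", "male_sex", "vessel_stenosis_rate", "nihss", "mprage",
             "smoking_history", "hypertension", "diabetes_mellitus",
             "dyslipidemia", "arteriosclerosis_obliterans",
             "coronary_artery_disease", "aspirin", "ticlopidine",
             "clopidogrel", "cilostazol", "warfarin", "heparin_argatroban",
             "statins"),
    type = c("continuous", "binary", "continuous", "continuous", "continuous",
             rep("binary", 13)),
    mean_normal = c(70.1, NA, 68.5, 1.2, 1.9, rep(NA, 13)),
    sd_normal = c(6.5, NA, 26.4, 2.68, 1.0, rep(NA, 13)),
    mean_abnormal = c(69.5, NA, 68.7, 3.0, 2.1, rep(NA, 13)),
    sd_abnormal = c(6.7, NA, 27.0, 5.7, 1.2, rep(NA, 13)),
    p_normal = c(NA, 0.925, NA, NA, NA, 0.600, 0.800, 0.433, 0.716, 0.133,
                 0.333, 0.900, 0.175, 0.158, 0.158, 0.000, 0.116, 0.666),
    p_abnormal = c(NA, 1.000, NA, NA, NA, 0.571, 0.904, 0.190, 0.857, 0.047,
                   0.238, 0.809, 0.333, 0.142, 0.142, 0.380, 0.190, 0.619),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic clinical-table generator
#'
#' @param n_normal,n_abnormal Patients per outcome class (at least 1 each).
#' @param missing_rate Probability in \[0,1) that a feature cell is missing.
#' @param effect_sizes Named list of additional class shifts applied to the
#'   abnormal class on top of the schema defaults: additive mean shift for
#'   continuous features, additive prevalence shift (clamped) for binary.
#' @param seed Integer RNG seed.
#' @return A `clinical_gen_config` object.
#' @export
clinical_gen_config <- function(n_normal, n_abnormal, missing_rate = 0,
                                effect_sizes = list(), seed = 1L) {
  if (n_normal < 1 || n_abnormal < 1) stop("need at least one patient per class")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  bad <- setdiff(names(effect_sizes), clinical_schema()$name)
  if (length(bad)) stop("unknown features in effect_sizes: ",
                        paste(bad, collapse = ", "))
  structure(list(n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 missing_rate = missing_rate,
                 effect_sizes = effect_sizes, seed = as.integer(seed)),
            class = "clinical_gen_config")
}

#' Generate a synthetic per-patient clinical table
#'
#' Draws the 18 schema variables class-conditionally (continuous features
#' from truncated normals, binary features as Bernoulli with the schema
#' prevalences), applies any extra configured effect shifts to the abnormal
#' class, and blanks cells completely at random at the configured rate.
#'
#' @param config A [clinical_gen_config()].
#' @return Data frame with `patient_id`, the 18 feature columns and an
#'   integer `outcome` label (0 = event-free, 1 = event).
#' @export
generate_clinical_table <- function(config) {
  stopifnot(inherits(config, "clinical_gen_config"))
  sch <- clinical_schema()
  n0 <- config$n_normal; n1 <- config$n_abnormal
  n <- n0 + n1
  outcome <- c(rep(0L, n0), rep(1L, n1))
  with_seed(config$seed, {
    tab <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sch))) {
      nm <- sch$name[i]
      eff <- if (!is.null(config$effect_sizes[[nm]]))
        config$effect_sizes[[nm]] else 0
      if (sch$type[i] == "continuous") {
        x0 <- stats::rnorm(n0, sch$mean_normal[i], sch$sd_normal[i])
        x1 <- stats::rnorm(n1, sch$mean_abnormal[i] + eff, sch$sd_abnormal[i])
        x <- pmax(c(x0, x1), 0)
      } else {
        p0 <- sch$p_normal[i]
        p1 <- min(0.995, max(0, sch$p_abnormal[i] + eff))
        x <- c(stats::rbinom(n0, 1L, p0), stats::rbinom(n1, 1L, p1))
      }
      tab[[nm]] <- x
    }
    if (config$missing_rate > 0) {
      for (nm in sch$name) {
        miss <- stats::runif(n) < config$missing_rate
        tab[[nm]][miss] <- NA
      }
    }
    tab$outcome <- outcome
    tab
  })
}

#' Generate a full synthetic study cohort (patch banks + clinical table)
#'
#' Builds one patch bank per patient and one clinical table with matching
#' patient ids.  Event patients receive a configurable fraction of
#' anomalous patches (the image signal); clinical class differences come
#' from the schema defaults plus `effect_sizes` (the clinical signal).  The
#' two signals are drawn independently.
#'
#' @param n_normal,n_abnormal Patients per class.
#' @param patches_per_patient Patches in each patient's bank.
#' @param patch_px Patch side in pixels.
#' @param lesion_patch_fraction Fraction of an event patient's patches that
#'   contain the anomalous texture.
#' @param anomaly_texture Texture of anomalous patches.
#' @param missing_rate,effect_sizes Passed to [clinical_gen_config()].
#' @param noise_sd Pixel noise (8-bit units).
#' @param seed Base RNG seed.
#' @return List with `clinical` (data frame) and `banks` (named list of
#'   `patch_bank` objects keyed by patient id).
#' @export
generate_cohort <- function(n_normal = 50L, n_abnormal = 21L,
                            patches_per_patient = 30L, patch_px = 64L,
                            lesion_patch_fraction = 0.3,
                            anomaly_texture = "hemorrhage_like",
                            missing_rate = 0.05, effect_sizes = list(),
                            noise_sd = 6, seed = 1L) {
  clin <- generate_clinical_table(clinical_gen_config(
    n_normal, n_abnormal, missing_rate = missing_rate,
    effect_sizes = effect_sizes, seed = seed))
  banks <- vector("list", nrow(clin))
  names(banks) <- clin$patient_id
  for (i in seq_len(nrow(clin))) {
    n_anom <- if (clin$outcome[i] == 1L)
      round(lesion_patch_fraction * patches_per_patient) else 0L
    cfg <- slide_gen_config(anomaly_texture = anomaly_texture,
                            noise_sd = noise_sd,
                            seed = (seed * 1000L + i) %% .Machine$integer.max)
    banks[[i]] <- generate_patch_bank(cfg, patches_per_patient - n_anom,
                                      n_anom, patch_px)
  }
  list(clinical = clin, banks = banks)
}
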