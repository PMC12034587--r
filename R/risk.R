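# Patient-level pathological risk score and anomaly heat maps.

#' Pathological risk score of a patient
#'
#' The mean of the patient's per-patch anomaly scores,
#' A_p = sum_{x in X} A(x) / |X|, where X pools the patches from all of the
#' patient's slides before averaging.  A_p is permutation-invariant and
#' bounded by the minimum and maximum patch score.
#'
#' @param scores Numeric vector of per-patch anomaly scores (the pooled
#'   patch group X), or a `patient_score_set` (list with `patch_scores`).
#' @return Nonnegative scalar A_p.
#' @export
patient_risk_score <- function(scores) {
  if (is.list(scores) && !is.null(scores$patch_scores))
    scores <- scores$patch_scores
  scores <- as.numeric(scores)
  if (length(scores) == 0) stop("patient has no scored patches; unscoreable")
  if (any(is.na(scores))) stop("patch scores contain NA")
  if (any(scores < 0)) stop("anomaly scores must be nonnegative")
  mean(scores)
}

#' Risk scores for a cohort of patch banks
#'
#' Scores every patient's patch bank under an anomaly model and aggregates
#' to per-patient risk scores.
#'
#' @param model A trained anomaly model (`plaq_autoencoder` or
#'   `plaq_fanogan`).
#' @param banks Named list of patch banks keyed by patient id.
#' @return Data frame with `patient_id`, `n_patches`, `risk_score`.
#' @export
score_cohort <- function(model, banks) {
  stopifnot(length(names(banks)) == length(banks))
  out <- data.frame(patient_id = names(banks),
                    n_patches = NA_integer_, risk_score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(banks)) {
    s <- score_patches(model, banks[[i]])
    out$n_patches[i] <- length(s)
    out$risk_score[i] <- patient_risk_score(s)
  }
  out
}

#' In-sample evaluation of the risk score as a standalone classifier
#'
#' Thresholds A_p by the in-sample Youden index and reports AUC and
#' confusion metrics.  All quantities are computed on the same patients
#' that determine the threshold, and the report is labelled as in-sample.
#'
#' @param risk Numeric vector of patient risk scores.
#' @param labels Binary outcome labels (1 = event).
#' @return List with `roc_auc`, `threshold`, `accuracy`, `sensitivity`,
#'   `specificity`, `f1` and `in_sample = TRUE`.
#' @export
evaluate_risk_score <- function(risk, labels) {
  thr <- youden_threshold(risk, labels)
  m <- evaluate_predictions(risk, labels, thr)
  c(m, list(in_sample = TRUE))
}

#' Render an anomaly heat map
#'
#' Produces a grayscale image at the segmentation-mask resolution in which
#' each patch footprint's brightness is the min-max normalized anomaly
#' score of the patch; brighter means more anomalous.  Pixels outside
#' tissue (or outside any patch footprint) are black.  Normalization
#' bounds default to the range of `scores` (per-cohort bounds can be
#' passed so that brightness is comparable across patients).
#'
#' @param records Patch manifest (data frame with `x0`, `y0`, `size_px`).
#' @param scores Per-patch anomaly scores aligned with `records`.
#' @param mask A `tissue_mask` (defines resolution and the tissue
#'   footprint), or NULL with `dims` and `downsample` given.
#' @param dims Level-0 slide dims `c(width, height)` when `mask` is NULL.
#' @param downsample Downsample factor when `mask` is NULL.
#' @param norm_range Numeric length-2 normalization bounds; defaults to
#'   `range(scores)`.
#' @return An `anomaly_heatmap`: numeric matrix in \[0,1\] with attributes
#'   `norm_range` and `downsample_factor`.
#' @export
render_heatmap <- function(records, scores, mask = NULL, dims = NULL,
                           downsample = NULL, norm_range = NULL) {
  if (nrow(records) != length(scores))
    stop("records and scores differ in length")
  if (any(is.na(scores))) stop("scores contain NA")
  if (!is.null(mask)) {
    ds <- mask$downsample_factor
    h <- nrow(mask$mask); w <- ncol(mask$mask)
  } else {
    if (is.null(dims) || is.null(downsample))
      stop("need mask, or dims plus downsample")
    ds <- downsample
    w <- dims[1] %/% ds; h <- dims[2] %/% ds
  }
  if (is.null(norm_range)) norm_range <- range(scores)
  span <- diff(norm_range)
  norm <- if (span > 0) (scores - norm_range[1]) / span
          else rep(1, length(scores))
  norm <- pmin(1, pmax(0, norm))
  hm <- matrix(0, h, w)
  for (i in seq_len(nrow(records))) {
    x0 <- records$x0[i] %/% ds; y0 <- records$y0[i] %/% ds
    px <- max(1L, records$size_px[i] %/% ds)
    rows <- (y0 + 1):min(h, y0 + px)
    cols <- (x0 + 1):min(w, x0 + px)
    hm[rows, cols] <- pmax(hm[rows, cols], norm[i])
  }
  if (!is.null(mask)) hm <- hm * mask$mask
  structure(hm, class = "anomaly_heatmap", norm_range = norm_range,
            downsample_factor = ds)
}

#' Write a heat map as PNG with a JSON normalization sidecar
#'
#' @param heatmap An `anomaly_heatmap`.
#' @param path Output PNG path; `<path>.json` records the normalization
#'   range and downsample factor.
#' @return Invisibly, the PNG path.
#' @export
write_heatmap_png <- function(heatmap, path) {
  png::writePNG(unclass(heatmap), path)
  jsonlite::write_json(list(norm_range = attr(heatmap, "norm_range"),
                            downsample_factor = attr(heatmap, "downsample_factor")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
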