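# Multimodal prognosis classification: the pathological risk score plus 18
# clinical variables feed a gradient-boosted binary classifier, evaluated
# by repeated stratified 7:3 patient-level splits with five-fold
# cross-validated grid search on log loss, Youden-index thresholding and
# normal-approximation 95% confidence intervals.

# round half up (0.5 -> 1), used for the 7:3 split sizes
round_half_up <- function(x) floor(x + 0.5)

#' Rank-concordance ROC-AUC
#'
#' The probability that a random event patient receives a higher score
#' than a random event-free patient, ties counted one half (equivalent to
#' the Mann-Whitney statistic via average ranks).
#'
#' @param scores Numeric predicted scores/probabilities.
#' @param labels Binary labels (1 = event).
#' @return AUC in \[0,1\]; NA if either class is absent.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index classification threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over candidate thresholds:
#' the midpoints between consecutive distinct sorted scores, plus -Inf and
#' +Inf sentinels.  A score is called positive when it is at least the
#' threshold.  Ties in J are broken toward the higher threshold (the more
#' specific operating point).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = event).
#' @return Numeric threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_j <- -Inf; best_t <- Inf
  for (t in cand) {
    pred <- as.integer(scores >= t)
    j <- sum(pred == 1 & labels == 1) / n1 +
         sum(pred == 0 & labels == 0) / n0 - 1
    if (j > best_j - 1e-12) {  # >= with tolerance: later (higher) wins ties
      if (j > best_j + 1e-12 || t > best_t) { best_j <- j; best_t <- t }
    }
  }
  best_t
}

#' Confusion-matrix metrics at a threshold
#'
#' @param scores Predicted probabilities/scores.
#' @param labels Binary labels (1 = event, the positive class).
#' @param threshold Scores at or above the threshold are called positive.
#' @return List with `roc_auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `f1` and `threshold`.  AUC is NA (flagged) on a one-class input.
#' @export
evaluate_predictions <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(roc_auc = roc_auc(scores, labels), accuracy = acc, sensitivity = sens,
       specificity = spec, f1 = f1, threshold = threshold)
}

#' Assemble the 19-feature table (clinical + risk score)
#'
#' Joins per-patient clinical rows with risk scores and imputes missing
#' cells with the column mean over observed values (binary indicators
#' likewise receive the observed mean, i.e. the prevalence).  The feature
#' column order is fixed and recorded in the `feature_cols` attribute.
#'
#' @param clinical Data frame with `patient_id`, the 18 schema feature
#'   columns and `outcome`.
#' @param risk Data frame with `patient_id` and `risk_score` (e.g. from
#'   [score_cohort()]), or NULL to build a clinical-only table.
#' @return Data frame with `patient_id`, features, `outcome`; attribute
#'   `feature_cols` lists the feature columns in order.
#' @export
assemble_features <- function(clinical, risk = NULL) {
  feat_cols <- clinical_schema()$name
  missing_cols <- setdiff(c("patient_id", feat_cols, "outcome"), names(clinical))
  if (length(missing_cols))
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  tab <- clinical[, c("patient_id", feat_cols, "outcome")]
  if (!is.null(risk)) {
    if (!all(c("patient_id", "risk_score") %in% names(risk)))
      stop("risk table needs patient_id and risk_score")
    if (!setequal(risk$patient_id, tab$patient_id))
      stop("clinical rows and risk scores cover different patients")
    tab$risk_score <- risk$risk_score[match(tab$patient_id, risk$patient_id)]
    feat_cols <- c(feat_cols, "risk_score")
  }
  for (nm in feat_cols) {
    x <- tab[[nm]]
    if (anyNA(x)) {
      if (all(is.na(x))) stop("feature ", nm, " has no observed values")
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      tab[[nm]] <- x
    }
  }
  tab <- tab[, c("patient_id", feat_cols, "outcome")]
  attr(tab, "feature_cols") <- feat_cols
  tab
}

feature_cols_of <- function(table) {
  fc <- attr(table, "feature_cols")
  if (is.null(fc)) fc <- setdiff(names(table), c("patient_id", "outcome"))
  fc
}

#' Stratified 7:3 patient-level split
#'
#' Samples a training set of round(ratio * N) patients, stratified by
#' outcome class (per-class sizes round half up, then adjusted in the
#' larger class to hit the overall size), with the complement as the test
#' set.  Deterministic for a fixed seed; every patient lands in exactly
#' one side.
#'
#' @param table Feature table with `patient_id` and `outcome`.
#' @param ratio Training fraction (default 0.7).
#' @param seed RNG seed.
#' @return A `split_plan`: list with `train_ids`, `test_ids`, `ratio`,
#'   `seed`.
#' @export
split_patients <- function(table, ratio = 0.7, seed = 1L) {
  ids <- table$patient_id
  y <- as.integer(table$outcome)
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least two patients per class")
  n <- length(ids)
  target <- round_half_up(ratio * n)
  with_seed(seed, {
    tr <- character(0)
    sizes <- integer(2)
    for (k in 0:1) sizes[k + 1] <- round_half_up(ratio * sum(y == k))
    # adjust in the larger class so the overall train size is exact
    excess <- sum(sizes) - target
    big <- which.max(c(sum(y == 0), sum(y == 1)))
    sizes[big] <- sizes[big] - excess
    for (k in 0:1) {
      cls <- ids[y == k]
      nk <- max(1L, min(length(cls) - 1L, sizes[k + 1]))
      tr <- c(tr, sample(cls, nk))
    }
    te <- setdiff(ids, tr)
    if (!any(y[ids %in% te] == 1) || !any(y[ids %in% te] == 0))
      stop("a class is absent from the test side")
    structure(list(train_ids = tr, test_ids = te, ratio = ratio,
                   seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' Default hyperparameter grid for the boosted classifier
#'
#' A small grid over tree depth, learning rate and boosting rounds, sized
#' for cohorts of tens of patients.
#'
#' @return List of parameter lists (each with `max_depth`, `eta`,
#'   `nrounds`, `lambda`).
#' @export
default_grid <- function() {
  g <- expand.grid(max_depth = c(2L, 3L), eta = c(0.1, 0.3),
                   nrounds = 60L, lambda = 1)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
}

# binary cross-entropy of predicted probabilities
log_loss <- function(p, y, eps = 1e-15) {
  p <- pmin(1 - eps, pmax(eps, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# deterministic stratified k-fold assignment
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    fold
  })
}

# ---- boosting backend interface --------------------------------------------
# A backend is a list(fit = function(x, y, par, seed) -> model,
#                     predict = function(model, x) -> probabilities).
# Backends are pluggable so another gradient-boosting family can be swapped
# in without pipeline changes.

xgboost_backend <- function() {
  list(
    name = "xgboost",
    fit = function(x, y, par, seed = 0L) {
      dtrain <- xgboost::xgb.DMatrix(data = x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = par$max_depth, eta = par$eta,
                      lambda = if (is.null(par$lambda)) 1 else par$lambda,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = par$nrounds, verbose = 0)
    },
    predict = function(model, x) {
      as.numeric(predict(model, xgboost::xgb.DMatrix(data = x)))
    }
  )
}

get_backend <- function(model = c("xgboost_like", "lightgbm_like")) {
  model <- match.arg(model)
  if (model == "xgboost_like") return(xgboost_backend())
  stop("no gradient-boosting backend of the lightgbm family is available; ",
       "use model = 'xgboost_like'")
}

#' Select the grid configuration with the lowest CV loss
#'
#' @param cv_losses Numeric vector of mean validation log losses, one per
#'   grid configuration.
#' @return Index of the first minimum.
#' @export
select_best_config <- function(cv_losses) {
  if (length(cv_losses) == 0) stop("empty grid")
  which.min(cv_losses)
}

#' Fit the boosted classifier with 5-fold CV grid search on log loss
#'
#' For every grid configuration, computes the mean validation log loss
#' over stratified folds, selects the argmin configuration, and refits it
#' on the full training set.  Fold assignment is seed-deterministic.
#'
#' @param train Feature table (training patients).
#' @param model Backend family, `"xgboost_like"` (default) or
#'   `"lightgbm_like"`.
#' @param grid List of hyperparameter lists; [default_grid()] by default.
#' @param folds Number of CV folds (default 5).
#' @param seed RNG seed for fold assignment and fitting.
#' @return A `plaq_classifier`: fitted backend model, chosen config, the
#'   per-config CV losses, and the feature column order.
#' @export
fit_classifier <- function(train, model = "xgboost_like",
                           grid = default_grid(), folds = 5L, seed = 1L) {
  if (length(grid) == 0) stop("empty grid")
  y <- as.integer(train$outcome)
  if (length(unique(y)) < 2) stop("training data contains a single class")
  fc <- feature_cols_of(train)
  x <- as.matrix(train[, fc, drop = FALSE])
  backend <- get_backend(model)
  fold <- stratified_folds(y, folds, seed)
  cv_losses <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    losses <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold != k; va <- fold == k
      if (length(unique(y[tr])) < 2) { losses[k] <- NA; next }
      fit <- backend$fit(x[tr, , drop = FALSE], y[tr], grid[[gi]], seed)
      losses[k] <- log_loss(backend$predict(fit, x[va, , drop = FALSE]), y[va])
    }
    cv_losses[gi] <- mean(losses, na.rm = TRUE)
  }
  best <- select_best_config(cv_losses)
  fit <- backend$fit(x, y, grid[[best]], seed)
  structure(list(fit = fit, backend = backend, config = grid[[best]],
                 cv_losses = cv_losses, feature_cols = fc),
            class = "plaq_classifier")
}

#' Predict event probabilities from a fitted classifier
#'
#' @param object A `plaq_classifier`.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return Numeric vector of event probabilities.
#' @export
predict.plaq_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  object$backend$predict(object$fit, x)
}

#' Total-gain feature importances of a fitted classifier
#'
#' Thin pass-through of the backend's gain-based importance.
#'
#' @param object A `plaq_classifier`.
#' @return Data frame with `feature` and `gain`, sorted decreasing.
#' @export
feature_importance <- function(object) {
  imp <- xgboost::xgb.importance(model = object$fit)
  data.frame(feature = imp$Feature, gain = imp$Gain,
             stringsAsFactors = FALSE)
}

#' Repeated split-train-test evaluation protocol
#'
#' For repetition i (seed = base seed + i): draw a stratified 7:3
#' patient-level split; run the CV grid search on the training patients;
#' compute the Youden threshold from the refit model's training-set
#' predictions; evaluate on the held-out patients.  A repetition whose
#' split fails class-presence preconditions is redrawn with a shifted seed
#' and the substitution recorded.  Aggregates are the per-metric mean with
#' a normal-approximation 95% CI (mean +/- 1.96 sd / sqrt(n)).
#'
#' @param table Feature table (all patients).
#' @param n_reps Number of repetitions (protocol default 100).
#' @param ratio Training fraction.
#' @param model Backend family.
#' @param grid Hyperparameter grid.
#' @param folds CV folds.
#' @param seed Base seed; the whole report is reproducible from it.
#' @param features Optional subset of feature columns (e.g. clinical-only).
#' @return An `evaluation_report`: per-repetition metric data frame,
#'   aggregate mean/CI table, `n_reps`, and the redrawn-seed log.
#' @export
repeated_evaluation <- function(table, n_reps = 100L, ratio = 0.7,
                                model = "xgboost_like", grid = default_grid(),
                                folds = 5L, seed = 1L, features = NULL) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (!is.null(features)) {
    keep <- c("patient_id", features, "outcome")
    table <- table[, keep]
    attr(table, "feature_cols") <- features
  }
  metrics <- c("roc_auc", "accuracy", "sensitivity", "specificity", "f1",
               "threshold")
  per_rep <- as.data.frame(matrix(NA_real_, n_reps, length(metrics),
                                  dimnames = list(NULL, metrics)))
  redrawn <- integer(0)
  for (i in seq_len(n_reps)) {
    rep_seed <- seed + i
    plan <- NULL
    repeat {
      plan <- tryCatch(split_patients(table, ratio, rep_seed),
                       error = function(e) NULL)
      if (!is.null(plan)) break
      redrawn <- c(redrawn, rep_seed)
      rep_seed <- rep_seed + 7919L  # redraw with a shifted seed
    }
    stopifnot(length(intersect(plan$train_ids, plan$test_ids)) == 0)
    tr <- table[table$patient_id %in% plan$train_ids, ]
    te <- table[table$patient_id %in% plan$test_ids, ]
    attr(tr, "feature_cols") <- feature_cols_of(table)
    attr(te, "feature_cols") <- feature_cols_of(table)
    clf <- fit_classifier(tr, model = model, grid = grid, folds = folds,
                          seed = rep_seed)
    thr <- youden_threshold(predict(clf, tr), tr$outcome)
    m <- evaluate_predictions(predict(clf, te), te$outcome, thr)
    per_rep[i, ] <- unlist(m[metrics])
  }
  agg <- do.call(rbind, lapply(metrics[metrics != "threshold"], function(nm) {
    v <- per_rep[[nm]]
    mu <- mean(v, na.rm = TRUE)
    se <- stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    data.frame(metric = nm, mean = mu, ci_lower = mu - 1.96 * se,
               ci_upper = mu + 1.96 * se, stringsAsFactors = FALSE)
  }))
  structure(list(per_rep = per_rep, aggregate = agg,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 redrawn_seeds = redrawn),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Repeated split evaluation: %d repetitions (base seed %d)\n",
              x$n_reps, x$seed))
  if (length(x$redrawn_seeds))
    cat("  redrawn split seeds:", paste(x$redrawn_seeds, collapse = ", "), "\n")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", agg$metric[i],
                agg$mean[i], agg$ci_lower[i], agg$ci_upper[i]))
  invisible(x)
}
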