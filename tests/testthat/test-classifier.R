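test_that("feature assembly imputes column means and yields 19 features", {
  clin <- generate_clinical_table(clinical_gen_config(6L, 4L, seed = 3L))
  clin$age <- c(60, 70, NA, 65, 72, 68, 71, 69, NA, 66)
  risk <- data.frame(patient_id = clin$patient_id,
                     risk_score = seq(0.01, 0.1, length.out = 10))
  tab <- assemble_features(clin, risk)
  expect_length(attr(tab, "feature_cols"), 19L)
  expect_false(anyNA(tab))
  obs <- c(60, 70, 65, 72, 68, 71, 69, 66)
  expect_equal(tab$age[3], mean(obs))
  expect_equal(tab$age[9], mean(obs))

  # without missing values the clinical columns pass through unchanged
  clin2 <- generate_clinical_table(clinical_gen_config(5L, 5L, seed = 4L))
  tab2 <- assemble_features(clin2, data.frame(patient_id = clin2$patient_id,
                                              risk_score = 0.5))
  expect_equal(tab2$nihss, clin2$nihss)

  # mismatched patients are an error
  expect_error(assemble_features(clin, risk[-1, ]), "different patients")
})

test_that("binary indicators are imputed with their observed prevalence", {
  clin <- generate_clinical_table(clinical_gen_config(10L, 5L, seed = 5L))
  clin$aspirin <- c(1, 1, 0, NA, 1, 0, 1, NA, 1, 1, 0, 1, 1, 0, 1)
  tab <- assemble_features(clin, NULL)
  expect_equal(tab$aspirin[4], mean(clin$aspirin, na.rm = TRUE))
  expect_length(attr(tab, "feature_cols"), 18L)
})

test_that("the 7:3 split is stratified, disjoint, exhaustive and deterministic", {
  clin <- generate_clinical_table(clinical_gen_config(50L, 21L, seed = 6L))
  tab <- assemble_features(clin, NULL)
  plan <- split_patients(tab, 0.7, seed = 10L)
  expect_length(plan$train_ids, 50L)   # round(0.7 * 71)
  expect_length(plan$test_ids, 21L)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0L)
  expect_setequal(c(plan$train_ids, plan$test_ids), tab$patient_id)
  plan2 <- split_patients(tab, 0.7, seed = 10L)
  expect_identical(plan, plan2)

  # class proportions within one patient of the stratified expectation
  for (sd in 1:100) {
    p <- split_patients(tab, 0.7, seed = sd)
    n1 <- sum(tab$outcome[tab$patient_id %in% p$train_ids])
    expect_lte(abs(n1 - 0.7 * 21), 1)
    expect_true(any(tab$outcome[tab$patient_id %in% p$test_ids] == 1))
    expect_true(any(tab$outcome[tab$patient_id %in% p$test_ids] == 0))
  }
  expect_error(split_patients(tab[tab$outcome == 0, ], 0.7, 1L), "class")
})

test_that("grid selection takes the configuration with the lowest CV loss", {
  expect_identical(select_best_config(c(0.60, 0.45, 0.52)), 2L)
  expect_error(select_best_config(numeric(0)), "empty")
})

test_that("CV grid search matches an exhaustive recomputation of log losses", {
  clin <- generate_clinical_table(clinical_gen_config(
    30L, 14L, effect_sizes = list(nihss = 3), seed = 7L))
  tab <- assemble_features(clin, NULL)
  grid <- default_grid()
  expect_length(grid, 4L)
  clf <- fit_classifier(tab, grid = grid, folds = 5L, seed = 9L)

  y <- tab$outcome
  x <- as.matrix(tab[, attr(tab, "feature_cols")])
  fold <- plaqrisk:::stratified_folds(y, 5L, 9L)
  backend <- plaqrisk:::xgboost_backend()
  losses <- sapply(grid, function(par) {
    mean(sapply(1:5, function(k) {
      fit <- backend$fit(x[fold != k, , drop = FALSE], y[fold != k], par, 9L)
      p <- backend$predict(fit, x[fold == k, , drop = FALSE])
      plaqrisk:::log_loss(p, y[fold == k])
    }))
  })
  expect_equal(clf$cv_losses, losses, tolerance = 1e-10)
  expect_identical(clf$config, grid[[which.min(losses)]])
})

test_that("a linearly separable cohort is classified perfectly", {
  clin <- generate_clinical_table(clinical_gen_config(20L, 10L, seed = 8L))
  tab <- assemble_features(clin, data.frame(
    patient_id = clin$patient_id,
    risk_score = ifelse(clin$outcome == 1, 10, 0)))
  plan <- split_patients(tab, 0.7, seed = 2L)
  tr <- tab[tab$patient_id %in% plan$train_ids, ]
  te <- tab[tab$patient_id %in% plan$test_ids, ]
  attr(tr, "feature_cols") <- attr(tab, "feature_cols")
  attr(te, "feature_cols") <- attr(tab, "feature_cols")
  clf <- fit_classifier(tr, seed = 2L)
  thr <- youden_threshold(predict(clf, tr), tr$outcome)
  m <- evaluate_predictions(predict(clf, te), te$outcome, thr)
  expect_equal(m$accuracy, 1)
  expect_error(fit_classifier(tr[tr$outcome == 0, ], seed = 1L), "single class")
})

test_that("the Youden threshold maximizes J and prefers the higher tie", {
  scores <- c(0.1, 0.3, 0.35, 0.8); labels <- c(0, 0, 1, 1)
  t <- youden_threshold(scores, labels)
  expect_equal(t, youden_bruteforce(scores, labels))
  expect_equal(t, 0.325)
  m <- evaluate_predictions(scores, labels, t)
  expect_equal(m$sensitivity + m$specificity - 1, 1)  # J = 1 when separable

  # constant scores carry no discrimination: J = 0
  tc <- youden_threshold(rep(0.5, 10), rep(c(0, 1), 5))
  mc <- evaluate_predictions(rep(0.5, 10), rep(c(0, 1), 5), tc)
  expect_equal(mc$sensitivity + mc$specificity - 1, 0)

  set.seed(77)
  for (i in 1:20) {
    s <- round(runif(20), 2); y <- rbinom(20, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(youden_threshold(s, y), youden_bruteforce(s, y))
  }
  expect_error(youden_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("confusion-matrix metrics reproduce definitional arithmetic", {
  # TP=5, FP=2, FN=1, TN=10 at threshold 0.5
  scores <- c(rep(0.9, 5), rep(0.1, 1), rep(0.9, 2), rep(0.1, 10))
  labels <- c(rep(1, 6), rep(0, 12))
  m <- evaluate_predictions(scores, labels, 0.5)
  expect_equal(m$sensitivity, 5 / 6)
  expect_equal(m$specificity, 10 / 12)
  expect_equal(m$accuracy, 15 / 18)
  expect_equal(m$f1, 10 / 13)

  perfect <- evaluate_predictions(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.5)
  expect_equal(unlist(perfect[c("roc_auc", "accuracy", "sensitivity",
                                "specificity", "f1")]),
               c(roc_auc = 1, accuracy = 1, sensitivity = 1,
                 specificity = 1, f1 = 1))
})

test_that("rank-concordance AUC matches pairwise counting and an independent library", {
  set.seed(88)
  for (i in 1:20) {
    s <- round(runif(30), 1)  # coarse rounding forces ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), auc_bruteforce(s, y))
  }
  s <- runif(50); y <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
  expect_true(is.na(roc_auc(s, rep(1, 50))))
})

test_that("the repeated protocol is reproducible and internally consistent", {
  clin <- generate_clinical_table(clinical_gen_config(
    25L, 12L, effect_sizes = list(nihss = 2), seed = 21L))
  tab <- assemble_features(clin, NULL)
  r1 <- repeated_evaluation(tab, n_reps = 5L, seed = 100L)
  r2 <- repeated_evaluation(tab, n_reps = 5L, seed = 100L)
  expect_identical(r1$per_rep, r2$per_rep)
  expect_equal(nrow(r1$per_rep), 5L)
  expect_true(all(r1$aggregate$ci_lower <= r1$aggregate$mean))
  expect_true(all(r1$aggregate$mean <= r1$aggregate$ci_upper))
  # CI formula recomputed from the stored per-repetition values
  v <- r1$per_rep$roc_auc
  mu <- mean(v); se <- sd(v) / sqrt(length(v))
  agg <- r1$aggregate[r1$aggregate$metric == "roc_auc", ]
  expect_equal(agg$mean, mu)
  expect_equal(agg$ci_lower, mu - 1.96 * se)
  expect_equal(agg$ci_upper, mu + 1.96 * se)
  # metric bounds
  mets <- as.matrix(r1$per_rep[, c("roc_auc", "accuracy", "sensitivity",
                                   "specificity", "f1")])
  expect_true(all(mets >= 0 & mets <= 1))
  expect_error(repeated_evaluation(tab, n_reps = 1L), "at least 2")
})

test_that("total-gain feature importances are exposed for a fitted model", {
  clin <- generate_clinical_table(clinical_gen_config(
    30L, 15L, effect_sizes = list(nihss = 4), seed = 23L))
  tab <- assemble_features(clin, NULL)
  clf <- fit_classifier(tab, seed = 3L)
  imp <- feature_importance(clf)
  expect_true(all(c("feature", "gain") %in% names(imp)))
  expect_true(nrow(imp) >= 1)
})
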