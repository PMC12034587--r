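# Shared fixtures, memoized so expensive objects (trained models, cohorts)
# are built once per test run.  All fixtures are seeded and deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Desk-scale profile used throughout the suite: 64 px patches, channel
# widths 8/16/32, 128-dim latent.
desk_spec <- function() autoencoder_spec(input_px = 64L,
                                         channels = c(8L, 16L, 32L),
                                         latent_dim = 128L)

# 500 normal training patches.
desk_train_bank <- function() fixture("desk_train_bank", function()
  generate_patch_bank(slide_gen_config(seed = 11L), 500L, 0L, 64L))

# held-out evaluation bank: 100 normal + 100 anomalous.
desk_eval_bank <- function() fixture("desk_eval_bank", function()
  generate_patch_bank(slide_gen_config(seed = 12L), 100L, 100L, 64L))

# The trained desk autoencoder (trained on normal patches only).
desk_ae <- function() fixture("desk_ae", function()
  train_autoencoder(desk_train_bank(), desk_spec(),
                    train_config(epochs = 20L, batch_size = 64L,
                                 learning_rate = 1e-3, seed = 101L)))

# 20 vs 20 patient cohort for the patient-level rank test.
rank_cohort <- function() fixture("rank_cohort", function()
  generate_cohort(n_normal = 20L, n_abnormal = 20L,
                  patches_per_patient = 20L, patch_px = 64L, seed = 31L))

# 50 normal / 21 abnormal study cohort, mirroring the classification-set
# sizes, with independent image and clinical signal.
study_cohort <- function() fixture("study_cohort", function()
  generate_cohort(n_normal = 50L, n_abnormal = 21L,
                  patches_per_patient = 20L, patch_px = 64L, seed = 41L))

# Risk scores of the study cohort under the desk autoencoder.
study_risk <- function() fixture("study_risk", function()
  score_cohort(desk_ae(), study_cohort()$banks))

# Assembled 19-feature table for the study cohort.
study_features <- function() fixture("study_features", function()
  assemble_features(study_cohort()$clinical, study_risk()))

# brute-force between-class-variance Otsu scan (independent oracle)
otsu_bruteforce <- function(h) {
  total <- sum(h)
  lv <- 0:255
  best <- -1; best_t <- 0L
  for (t in 0:255) {
    w0 <- sum(h[1:(t + 1)])
    w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * lv[1:(t + 1)]) / w0
    mu1 <- sum(h[(t + 2):256] * lv[(t + 2):256]) / w1
    bcv <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
    if (bcv > best + 1e-15) { best <- bcv; best_t <- t }
  }
  best_t
}

# brute-force pairwise-concordance AUC (independent oracle)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force Youden scan over candidate thresholds (independent oracle)
youden_bruteforce <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  js <- sapply(cand, function(t) {
    pred <- as.integer(scores >= t)
    sum(pred == 1 & labels == 1) / sum(labels == 1) +
      sum(pred == 0 & labels == 0) / sum(labels == 0) - 1
  })
  best <- max(js)
  max(cand[js >= best - 1e-12])  # highest threshold among ties
}

# exhaustive window enumeration on a kronecker-expanded full-resolution
# mask (independent patch-grid oracle)
patch_grid_bruteforce <- function(mask, ds, W, H, p, st, minfrac) {
  full <- kronecker(mask * 1, matrix(1, ds, ds))
  out <- NULL
  for (y0 in seq(0, H - p, by = st)) for (x0 in seq(0, W - p, by = st)) {
    fr <- mean(full[y0 + seq_len(p), x0 + seq_len(p)])
    if (fr >= minfrac) out <- rbind(out, c(x0, y0, fr))
  }
  out
}
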