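test_that("reconstruction score obeys its zero, unit and bounded limits", {
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(anomaly_score_recon(x, x), 0)
  expect_equal(anomaly_score_recon(array(1, c(4, 4, 3)), array(0, c(4, 4, 3))), 1)
  # inputs in [0,1] bound the score by 1
  y <- array(runif(8 * 8 * 3), c(8, 8, 3))
  s <- anomaly_score_recon(x, y)
  expect_gte(s, 0); expect_lte(s, 1)
  expect_error(anomaly_score_recon(x, array(0, c(4, 4, 3))), "mismatch")
})

test_that("izif score reduces to the reconstruction score when features agree", {
  set.seed(31)
  x <- runif(48); xg <- runif(48); f <- rnorm(7)
  expect_equal(anomaly_score_izif(x, xg, f, f), anomaly_score_recon(x, xg))
  expect_equal(anomaly_score_izif(x, x, f, f), 0)
})

test_that("autoencoder training is seed-deterministic and guards against label leakage", {
  bank <- generate_patch_bank(slide_gen_config(seed = 51L), 32L, 0L, 32L)
  spec <- autoencoder_spec(32L, c(4L, 8L, 8L), 16L)
  cfg <- train_config(epochs = 3L, batch_size = 16L, learning_rate = 1e-3,
                      seed = 77L)
  m1 <- train_autoencoder(bank, spec, cfg)
  m2 <- train_autoencoder(bank, spec, cfg)
  expect_identical(m1$loss_curve, m2$loss_curve)
  expect_identical(m1$params, m2$params)

  mixed <- generate_patch_bank(slide_gen_config(seed = 52L), 10L, 2L, 32L)
  expect_error(train_autoencoder(mixed, spec, cfg), "normal material only")
})

test_that("the autoencoder overfits a repeated constant patch to near-zero error", {
  pal <- plaq_palettes()
  one <- array(rep(pal$tissue / 255, each = 32 * 32), c(32, 32, 3))
  pix <- array(rep(one, 10), c(32, 32, 3, 10))
  m <- train_autoencoder(pix, autoencoder_spec(32L, c(4L, 8L, 8L), 16L),
                         train_config(epochs = 200L, batch_size = 10L,
                                      learning_rate = 0.03, seed = 2L))
  expect_lt(utils::tail(m$loss_curve, 1), 1e-3)
})

test_that("trained autoencoder scores separate held-out anomalous patches", {
  m <- desk_ae()
  bank <- desk_eval_bank()
  s <- score_patches(m, bank)
  expect_true(all(s >= 0))
  expect_true(all(s <= 1))  # scale contract for [0,1] inputs
  y <- as.integer(bank$label == "anomalous")
  expect_gte(roc_auc(s, y), 0.90)
  # single-patch scoring agrees with the batch path
  expect_equal(autoencoder_score(m, bank$pixels[, , , 1]), s[1])
})

test_that("GAN checkpoint selection and encoder early stopping follow their rules", {
  expect_identical(select_best_checkpoint(c(40, 25, 31)), 2L)
  # a loss flat for the full patience window stops at that epoch
  expect_identical(plaqrisk:::early_stop_epoch(rep(0.5, 40), 30L), 31L)
  expect_true(is.na(plaqrisk:::early_stop_epoch(seq(1, 0.1, length.out = 40), 30L)))
})

test_that("a small f-AnoGAN ranks anomalous patches above normal ones", {
  tr <- generate_patch_bank(slide_gen_config(seed = 21L), 200L, 0L, 32L)
  te <- generate_patch_bank(slide_gen_config(seed = 22L), 50L, 50L, 32L)
  spec <- fanogan_spec(input_px = 32L, channels = c(8L, 16L, 32L),
                       latent_dim = 64L, feature_dim = 64L)
  m <- train_fanogan(tr, spec,
                     train_config(epochs = 10L, batch_size = 32L,
                                  learning_rate = 5e-5,
                                  optimizer = "rmsprop", seed = 3L),
                     n_critic = 3L, fid_every = 5L, encoder_epochs = 12L)
  s <- score_patches(m, te)
  expect_true(all(s >= 0))
  expect_gt(median(s[te$label == "anomalous"]),
            median(s[te$label == "normal"]))
  # the kept checkpoint attains the minimum of the FID trace
  expect_equal(m$best_fid, min(m$fid_trace))
  expect_equal(fanogan_score(m, te$pixels[, , , 1]), s[1])
  # anomalous patches must not enter GAN training either
  expect_error(train_fanogan(te, spec), "normal material only")
})

test_that("the Frechet distance is zero between identical Gaussians and grows with separation", {
  s <- diag(3)
  expect_equal(frechet_distance(rep(0, 3), s, rep(0, 3), s), 0)
  d1 <- frechet_distance(rep(0, 3), s, rep(1, 3), s)
  expect_equal(d1, 3)  # mean term only
  d2 <- frechet_distance(rep(0, 3), s, rep(2, 3), s)
  expect_gt(d2, d1)
})
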