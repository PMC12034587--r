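# f-AnoGAN (izif variant): a WGAN-GP generator/critic pair trained on
# normal patches, followed by an encoder mapping images into the frozen
# generator's latent space.  The anomaly score combines the image residual
# with the residual of the critic's penultimate-layer features.

#' f-AnoGAN architecture specification
#'
#' @param input_px Input patch side (multiple of 8).
#' @param channels Three channel widths shared by generator, critic and
#'   encoder trunks.
#' @param latent_dim Latent dimension (1024 at full scale).
#' @param feature_dim Dimension of the critic feature layer f(.) (the layer
#'   before the critic's final scalar output).
#' @return A `fanogan_spec` object.
#' @export
fanogan_spec <- function(input_px = 256L, channels = c(32L, 64L, 128L),
                         latent_dim = 1024L, feature_dim = 256L) {
  if (input_px %% 8 != 0 || input_px < 8) stop("input_px must be a multiple of 8")
  if (length(channels) != 3 || any(channels < 1)) stop("need three channel widths")
  if (latent_dim < 1 || feature_dim < 1) stop("latent_dim and feature_dim must be positive")
  structure(list(input_px = as.integer(input_px),
                 channels = as.integer(channels),
                 latent_dim = as.integer(latent_dim),
                 feature_dim = as.integer(feature_dim)),
            class = "fanogan_spec")
}

#' izif anomaly score from raw tensors
#'
#' A(x) = |x - G(E(x))|^2 / n + |f(x) - f(G(E(x)))|^2 / n_d, where n is
#' the number of pixel-channel entries of x and n_d the critic feature
#' dimension.  Both terms are normalized squared Euclidean norms with
#' implicit equal weighting.
#'
#' @param x Input patch (any numeric array/vector).
#' @param x_gen Generated reconstruction G(E(x)), same shape as `x`.
#' @param f_x,f_gen Critic feature vectors of `x` and `x_gen`.
#' @return Nonnegative scalar score.
#' @export
anomaly_score_izif <- function(x, x_gen, f_x, f_gen) {
  if (length(x) != length(x_gen)) stop("image shape mismatch")
  if (length(f_x) != length(f_gen)) stop("feature shape mismatch")
  mean((as.numeric(x) - as.numeric(x_gen))^2) +
    mean((as.numeric(f_x) - as.numeric(f_gen))^2)
}

#' Select the checkpoint with the lowest FID
#'
#' @param fids Numeric vector of FID values, one per checkpoint.
#' @return Index of the first minimum.
#' @export
select_best_checkpoint <- function(fids) {
  if (length(fids) == 0) stop("no checkpoints")
  which.min(fids)
}

# ---- lightweight FID --------------------------------------------------------

# Fixed random-projection CNN embedding used for checkpoint selection. The
# reference embedding network for FID is a heavyweight pretrained model;
# checkpoint selection only needs a consistent feature space, so a small
# frozen random CNN (seeded independently of training) stands behind the
# same interface.
fid_embedder <- function(input_px, dim = 24L, seed = 420L) {
  layers <- list(
    nn_layer("conv", h = input_px, w = input_px, cin = 3L, cout = 8L),
    nn_layer("lrelu"),
    nn_layer("pool", h = input_px, w = input_px, cin = 8L),
    nn_layer("conv", h = input_px / 2, w = input_px / 2, cin = 8L, cout = 12L),
    nn_layer("lrelu"),
    nn_layer("pool", h = input_px / 2, w = input_px / 2, cin = 12L),
    nn_layer("dense", din = (input_px / 4)^2 * 12, dout = dim)
  )
  params <- with_seed(seed, nn_init_params(layers))
  list(layers = layers, params = params, dim = dim)
}

embed_images <- function(embedder, X) {
  out <- matrix(0, embedder$dim, ncol(X))
  for (b0 in seq(1L, ncol(X), by = 64L)) {
    idx <- b0:min(ncol(X), b0 + 63L)
    out[, idx] <- nn_forward(embedder$layers, embedder$params,
                             X[, idx, drop = FALSE], keep_cache = FALSE)$out
  }
  out
}

#' Frechet distance between two Gaussian feature summaries
#'
#' d^2 = |mu1 - mu2|^2 + tr(S1 + S2 - 2 (S1^(1/2) S2 S1^(1/2))^(1/2)),
#' the distance underlying the FID metric.
#'
#' @param mu1,mu2 Mean vectors.
#' @param s1,s2 Covariance matrices.
#' @return Nonnegative scalar.
#' @export
frechet_distance <- function(mu1, s1, mu2, s2) {
  sqrtm_sym <- function(m) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    v <- pmax(e$values, 0)
    e$vectors %*% (sqrt(v) * t(e$vectors))
  }
  s1h <- sqrtm_sym(s1)
  mid <- sqrtm_sym(s1h %*% s2 %*% s1h)
  d2 <- sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) - 2 * sum(diag(mid))
  max(d2, 0)
}

fid_score <- function(embedder, X_real, X_gen) {
  fr <- embed_images(embedder, X_real)
  fg <- embed_images(embedder, X_gen)
  frechet_distance(rowMeans(fr), stats::cov(t(fr)),
                   rowMeans(fg), stats::cov(t(fg)))
}

# ---- training ---------------------------------------------------------------

# Gradient of the WGAN-GP penalty term wrt critic parameters, via a
# symmetric finite-difference Hessian-vector product: for interpolates Xi
# with input gradients g_s (norms ns), d/dtheta sum_s lambda/B (ns-1)^2 =
# d/dtheta sum_s c_s D_theta(Xi_s +- eps v_s) with v_s = g_s/ns and
# c_s = 2 lambda (ns - 1) / B, evaluated as two extra backward passes.
gp_param_grad <- function(layers, params, Xi, lambda, batch, eps = 1e-4) {
  fw <- nn_forward(layers, params, Xi)
  ones <- matrix(1, 1, ncol(Xi))
  bw <- nn_backward(layers, params, fw, ones, want_dx = TRUE)
  g <- bw$dx
  ns <- sqrt(colSums(g^2))
  ns <- pmax(ns, 1e-12)
  v <- sweep(g, 2, ns, "/")
  cs <- 2 * lambda * (ns - 1) / batch
  grad_at <- function(Xp, coefs) {
    fwp <- nn_forward(layers, params, Xp)
    nn_backward(layers, params, fwp, matrix(coefs, 1), want_dx = FALSE)$dparams
  }
  gp <- (grad_at(Xi + eps * v, cs / (2 * eps)) -
         grad_at(Xi - eps * v, cs / (2 * eps)))
  list(grad = gp, penalty = lambda * mean((ns - 1)^2))
}

#' Train the f-AnoGAN model (WGAN-GP, then izif encoder)
#'
#' Two-phase training on normal patches only.  Phase one trains the
#' generator/critic pair with the Wasserstein loss and gradient penalty;
#' at a fixed epoch interval a lightweight-FID checkpoint is recorded and
#' the checkpoint with the lowest FID on the training set is kept.  Phase
#' two trains the encoder izif-style against the frozen generator and
#' critic features, with early stopping once the encoder loss has not
#' improved for `encoder_patience` consecutive epochs.
#'
#' @param patches Normal-only patch input (bank, array or matrix).
#' @param spec A [fanogan_spec()].
#' @param cfg A [train_config()]; full-scale defaults for this model are
#'   RMSprop at learning rate 5e-5.
#' @param n_critic Critic updates per generator update.
#' @param gp_lambda Gradient-penalty weight.
#' @param fid_every Epoch interval between FID checkpoints.
#' @param encoder_epochs,encoder_lr,encoder_patience izif-phase settings;
#'   the encoder uses Adam.
#' @param feature_weight Weight kappa of the critic-feature residual in the
#'   encoder loss (the score formula itself always weights terms equally).
#' @param verbose Print progress.
#' @return A `plaq_fanogan`: generator, critic and encoder layer lists and
#'   parameters, the FID trace, and the encoder loss curve.
#' @export
train_fanogan <- function(patches, spec, cfg = train_config(
                            optimizer = "rmsprop", learning_rate = 5e-5),
                          n_critic = 5L, gp_lambda = 10,
                          fid_every = 5L, encoder_epochs = 50L,
                          encoder_lr = 1e-3, encoder_patience = 30L,
                          feature_weight = 1, verbose = FALSE) {
  if (inherits(patches, "patch_bank") && any(patches$label == "anomalous"))
    stop("training bank contains anomalous-labelled patches; the anomaly model must see normal material only")
  X <- as_patch_matrix(patches, spec$input_px)
  n <- ncol(X)
  gl <- gan_generator_layers(spec$input_px, spec$channels, spec$latent_dim)
  dl <- gan_critic_layers(spec$input_px, spec$channels, spec$feature_dim)
  el <- gan_encoder_layers(spec$input_px, spec$channels, spec$latent_dim)
  fl <- gan_feature_layers(dl)
  embedder <- fid_embedder(spec$input_px)
  with_seed(cfg$seed, {
    gp_ <- nn_init_params(gl)
    dp_ <- nn_init_params(dl)
    opt_g <- make_optimizer(cfg$optimizer, length(gp_), cfg$learning_rate)
    opt_d <- make_optimizer(cfg$optimizer, length(dp_), cfg$learning_rate)
    B <- min(cfg$batch_size, n)
    best_fid <- Inf; best_gp <- gp_; best_dp <- dp_
    fid_trace <- numeric(0)
    crit_i <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = B)) {
        idx <- ord[b0:min(n, b0 + B - 1L)]
        Xr <- X[, idx, drop = FALSE]
        bsz <- length(idx)
        Z <- matrix(stats::rnorm(spec$latent_dim * bsz), spec$latent_dim)
        Xf <- nn_forward(gl, gp_, Z, keep_cache = FALSE)$out
        # critic step: maximize D(real) - D(fake)  (minimize the negative)
        fw_r <- nn_forward(dl, dp_, Xr)
        gr_r <- nn_backward(dl, dp_, fw_r, matrix(-1 / bsz, 1, bsz),
                            want_dx = FALSE)$dparams
        fw_f <- nn_forward(dl, dp_, Xf)
        gr_f <- nn_backward(dl, dp_, fw_f, matrix(1 / bsz, 1, bsz),
                            want_dx = FALSE)$dparams
        epsm <- matrix(stats::runif(bsz), nrow(Xr), bsz, byrow = TRUE)
        Xi <- epsm * Xr + (1 - epsm) * Xf
        gp_res <- gp_param_grad(dl, dp_, Xi, gp_lambda, bsz)
        dp_ <- opt_d(dp_, gr_r + gr_f + gp_res$grad)
        crit_i <- crit_i + 1L
        if (crit_i %% n_critic == 0L) {
          # generator step: minimize -D(G(z))
          Z <- matrix(stats::rnorm(spec$latent_dim * bsz), spec$latent_dim)
          fw_g <- nn_forward(gl, gp_, Z)
          fw_d <- nn_forward(dl, dp_, fw_g$out)
          dx <- nn_backward(dl, dp_, fw_d, matrix(-1 / bsz, 1, bsz),
                            want_dx = TRUE)$dx
          gr_g <- nn_backward(gl, gp_, fw_g, dx, want_dx = FALSE)$dparams
          gp_ <- opt_g(gp_, gr_g)
        }
      }
      if (ep %% fid_every == 0L || ep == cfg$epochs) {
        ns <- min(n, 128L)
        Z <- matrix(stats::rnorm(spec$latent_dim * ns), spec$latent_dim)
        Xg <- nn_forward(gl, gp_, Z, keep_cache = FALSE)$out
        fid <- fid_score(embedder, X[, seq_len(ns), drop = FALSE], Xg)
        fid_trace <- c(fid_trace, fid)
        if (verbose) message(sprintf("epoch %d: FID %.3f", ep, fid))
        if (fid < best_fid) { best_fid <- fid; best_gp <- gp_; best_dp <- dp_ }
      }
    }
    gp_ <- best_gp; dp_ <- best_dp

    # ---- izif encoder against frozen G and f ----
    ep_ <- nn_init_params(el)
    opt_e <- make_optimizer("adam", length(ep_), encoder_lr)
    fp_ <- dp_[seq_len(nn_n_params(fl))]   # feature net = critic prefix
    nd <- spec$feature_dim
    npix <- spec$input_px^2 * 3
    enc_curve <- numeric(0)
    best <- Inf; bad <- 0L
    for (ep in seq_len(encoder_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, n, by = B)) {
        idx <- ord[b0:min(n, b0 + B - 1L)]
        Xb <- X[, idx, drop = FALSE]
        bsz <- length(idx)
        fw_e <- nn_forward(el, ep_, Xb)
        fw_g <- nn_forward(gl, gp_, fw_e$out)
        Xrec <- fw_g$out
        f_x <- nn_forward(fl, fp_, Xb, keep_cache = FALSE)$out
        fw_fr <- nn_forward(fl, fp_, Xrec)
        f_r <- fw_fr$out
        loss <- mean(colMeans((Xb - Xrec)^2)) +
          feature_weight * mean(colMeans((f_x - f_r)^2))
        d_rec <- -2 * (Xb - Xrec) / npix / bsz
        d_fr <- -2 * feature_weight * (f_x - f_r) / nd / bsz
        d_rec <- d_rec + nn_backward(fl, fp_, fw_fr, d_fr, want_dx = TRUE)$dx
        d_lat <- nn_backward(gl, gp_, fw_g, d_rec, want_dx = TRUE)$dx
        gr_e <- nn_backward(el, ep_, fw_e, d_lat, want_dx = FALSE)$dparams
        ep_ <- opt_e(ep_, gr_e)
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      enc_curve[ep] <- ep_loss / nb
      if (verbose) message(sprintf("encoder epoch %d: loss %.6f", ep, enc_curve[ep]))
      stop_at <- early_stop_epoch(enc_curve, encoder_patience)
      if (!is.na(stop_at)) break
    }
    structure(list(generator = list(layers = gl, params = gp_),
                   critic = list(layers = dl, params = dp_),
                   encoder = list(layers = el, params = ep_),
                   feature = list(layers = fl, params = fp_),
                   spec = spec, cfg = cfg, fid_trace = fid_trace,
                   best_fid = best_fid, encoder_loss = enc_curve),
              class = "plaq_fanogan")
  })
}

#' izif anomaly score of one patch under a trained f-AnoGAN
#'
#' @param model A `plaq_fanogan`.
#' @param patch A single patch.
#' @return Nonnegative scalar score.
#' @export
fanogan_score <- function(model, patch) {
  X <- as_patch_matrix(patch, model$spec$input_px)
  if (ncol(X) != 1) stop("fanogan_score expects a single patch; use score_patches for batches")
  score_patches(model, X)[1]
}

#' @export
score_patches.plaq_fanogan <- function(model, patches) {
  X <- as_patch_matrix(patches, model$spec$input_px)
  for (comp in c("generator", "encoder", "feature"))
    if (is.null(model[[comp]])) stop("model is missing its ", comp, " component")
  scores <- numeric(ncol(X))
  for (b0 in seq(1L, ncol(X), by = 64L)) {
    idx <- b0:min(ncol(X), b0 + 63L)
    Xb <- X[, idx, drop = FALSE]
    Zb <- nn_forward(model$encoder$layers, model$encoder$params, Xb,
                     keep_cache = FALSE)$out
    Xg <- nn_forward(model$generator$layers, model$generator$params, Zb,
                     keep_cache = FALSE)$out
    fx <- nn_forward(model$feature$layers, model$feature$params, Xb,
                     keep_cache = FALSE)$out
    fg <- nn_forward(model$feature$layers, model$feature$params, Xg,
                     keep_cache = FALSE)$out
    scores[idx] <- colMeans((Xb - Xg)^2) + colMeans((fx - fg)^2)
  }
  scores
}
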