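# Reconstruction-based anomaly detection: a convolutional autoencoder
# trained on patches from event-free patients only.  The anomaly score of a
# patch is the mean squared error between the patch and its reconstruction,
# averaged over every pixel-channel entry.

#' Autoencoder architecture specification
#'
#' Encoder: three 3x3 convolution layers, each followed by ReLU and 2x2 max
#' pooling; the final feature map is flattened into a dense latent
#' representation.  Decoder: a dense expansion back to the feature map and
#' three stride-2 transposed convolutions, the first two followed by ReLU
#' and the last by a sigmoid, so reconstructions live in \[0,1\].
#'
#' The default profile (256 px input, channel widths 32/64/128, 512-dim
#' latent) is the full-scale model; the desk profile (64 px, 8/16/32,
#' 128-dim) trains in minutes on one CPU and is used throughout the test
#' suite.
#'
#' @param input_px Input patch side (multiple of 8).
#' @param channels Integer vector of three encoder channel widths.
#' @param latent_dim Latent dimension.
#' @return An `autoencoder_spec` object.
#' @export
autoencoder_spec <- function(input_px = 256L, channels = c(32L, 64L, 128L),
                             latent_dim = 512L) {
  if (input_px %% 8 != 0 || input_px < 8) stop("input_px must be a multiple of 8")
  if (length(channels) != 3 || any(channels < 1)) stop("need three channel widths")
  if (latent_dim < 1) stop("latent_dim must be positive")
  structure(list(input_px = as.integer(input_px),
                 channels = as.integer(channels),
                 latent_dim = as.integer(latent_dim)),
            class = "autoencoder_spec")
}

#' Training configuration
#'
#' Defaults follow the full-scale training protocol for the autoencoder:
#' 300 epochs, batch size 64, learning rate 0.001, Adam.
#'
#' @param epochs,batch_size,learning_rate,optimizer,early_stop_patience,seed
#'   Standard training hyperparameters; `optimizer` is `"adam"` or
#'   `"rmsprop"`.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 300L, batch_size = 64L,
                         learning_rate = 0.001,
                         optimizer = c("adam", "rmsprop"),
                         early_stop_patience = 30L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("epochs, batch_size and learning_rate must be positive")
  if (early_stop_patience < 1) stop("early_stop_patience must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Reconstruction anomaly score
#'
#' The score of a patch given its reconstruction: the mean of squared
#' differences over all n pixel-channel entries,
#' A(x) = |x - x_hat|^2 / n.  Zero iff the reconstruction is exact; for
#' inputs and reconstructions in \[0,1\] the score is at most 1.
#'
#' @param x,x_hat Numeric arrays/vectors of identical shape.
#' @return Nonnegative scalar score.
#' @export
anomaly_score_recon <- function(x, x_hat) {
  if (length(x) != length(x_hat)) stop("shape mismatch between input and reconstruction")
  mean((as.numeric(x) - as.numeric(x_hat))^2)
}

# Coerce patch input (array p x p x 3 [x n], patch_bank, or feature matrix)
# into the (features x n) matrix the engine consumes.
as_patch_matrix <- function(x, input_px) {
  nfeat <- input_px^2 * 3
  if (inherits(x, "patch_bank")) x <- x$pixels
  if (is.matrix(x)) {
    if (nrow(x) != nfeat) stop("patch feature dimension does not match model input size")
    return(x)
  }
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3, 4)))
    stop("patches must be a p x p x 3 [x n] array, patch_bank, or matrix")
  if (d[1] != input_px || d[2] != input_px || d[3] != 3)
    stop("patch dimensions do not match model input size")
  n <- if (length(d) == 4) d[4] else 1L
  matrix(x, nfeat, n)
}

#' Train the convolutional autoencoder on normal patches
#'
#' Minimizes reconstruction MSE over the training bank with mini-batch
#' gradient descent.  Training is restricted to normal material: a patch
#' bank containing any patch labelled `"anomalous"` is rejected, guarding
#' against label leakage into the anomaly model.  Fully deterministic for a
#' fixed `cfg$seed`.
#'
#' @param patches A `patch_bank`, p x p x 3 x n array, or feature matrix of
#'   normal patches with values in \[0,1\].
#' @param spec An [autoencoder_spec()].
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return A `plaq_autoencoder`: list with `layers`, `params`, `spec`,
#'   `cfg` and `loss_curve` (mean training MSE per epoch).
#' @export
train_autoencoder <- function(patches, spec = autoencoder_spec(),
                              cfg = train_config(), verbose = FALSE) {
  if (inherits(patches, "patch_bank") && any(patches$label == "anomalous"))
    stop("training bank contains anomalous-labelled patches; the anomaly model must see normal material only")
  X <- as_patch_matrix(patches, spec$input_px)
  n <- ncol(X)
  if (n < 1) stop("need at least one training patch")
  layers <- ae_layers(spec$input_px, spec$channels, spec$latent_dim)
  with_seed(cfg$seed, {
    params <- nn_init_params(layers)
    opt <- make_optimizer(cfg$optimizer, length(params), cfg$learning_rate)
    loss_curve <- numeric(0)
    best <- Inf; bad <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        xb <- X[, idx, drop = FALSE]
        fw <- nn_forward(layers, params, xb)
        r <- fw$out - xb
        loss <- mean(r^2)
        d_out <- 2 * r / length(r)
        bw <- nn_backward(layers, params, fw, d_out, want_dx = FALSE)
        params <- opt(params, bw$dparams)
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      loss_curve[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d: mse %.6f", ep, loss_curve[ep]))
      if (loss_curve[ep] < best) { best <- loss_curve[ep]; bad <- 0L }
      else { bad <- bad + 1L; if (bad >= cfg$early_stop_patience) break }
    }
    structure(list(layers = layers, params = params, spec = spec, cfg = cfg,
                   loss_curve = loss_curve),
              class = "plaq_autoencoder")
  })
}

#' Reconstruct patches through a trained autoencoder
#'
#' @param model A `plaq_autoencoder`.
#' @param patches Patch input (see [train_autoencoder()]).
#' @return Matrix of reconstructions, one column per patch.
#' @export
reconstruct <- function(model, patches) {
  X <- as_patch_matrix(patches, model$spec$input_px)
  out <- matrix(0, nrow(X), ncol(X))
  for (b0 in seq(1L, ncol(X), by = 64L)) {
    idx <- b0:min(ncol(X), b0 + 63L)
    out[, idx] <- nn_forward(model$layers, model$params,
                             X[, idx, drop = FALSE], keep_cache = FALSE)$out
  }
  out
}

#' Anomaly score of one patch under a trained autoencoder
#'
#' @param model A `plaq_autoencoder`.
#' @param patch A single patch (p x p x 3 array, or length-3p^2 vector).
#' @return Nonnegative scalar anomaly score.
#' @export
autoencoder_score <- function(model, patch) {
  X <- as_patch_matrix(patch, model$spec$input_px)
  if (ncol(X) != 1) stop("autoencoder_score expects a single patch; use score_patches for batches")
  xh <- reconstruct(model, X)
  anomaly_score_recon(X, xh)
}

#' Anomaly scores for a bank of patches
#'
#' @param model A trained `plaq_autoencoder` or `plaq_fanogan`.
#' @param patches Patch input.
#' @return Numeric vector of per-patch anomaly scores.
#' @export
score_patches <- function(model, patches) {
  UseMethod("score_patches")
}

#' @export
score_patches.plaq_autoencoder <- function(model, patches) {
  X <- as_patch_matrix(patches, model$spec$input_px)
  xh <- reconstruct(model, X)
  colMeans((X - xh)^2)
}
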