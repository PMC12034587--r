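#' @useDynLib plaqrisk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- sequential-network plumbing -------------------------------------------
# A network is a list of layer descriptors consumed by the C++ engine.
# Parameters live in one flat numeric vector; the layout is layer-by-layer
# (weights, then bias) so that a prefix of the vector parameterizes a
# truncated layer list.

nn_layer <- function(type, ...) c(list(type = type), list(...))

nn_param_info <- function(layers) nn_param_info_cpp(layers)

nn_n_params <- function(layers) as.integer(nn_param_info(layers)$n_params)

# He-normal weight init, zero biases. Uses the calling RNG state.
nn_init_params <- function(layers) {
  info <- nn_param_info(layers)
  params <- numeric(info$n_params)
  for (i in seq_along(info$offset)) {
    nw <- info$wsize[i]
    if (nw == 0L) next
    off <- info$offset[i]
    sd <- sqrt(2 / max(1L, info$fan_in[i]))
    params[off + seq_len(nw)] <- stats::rnorm(nw, sd = sd)
    # biases stay zero
  }
  params
}

nn_forward <- function(layers, params, x, keep_cache = TRUE) {
  nn_forward_cpp(layers, params, x, keep_cache)
}

nn_backward <- function(layers, params, fw, d_out, want_dx = TRUE) {
  nn_backward_cpp(layers, params, fw$caches, fw$poolidx, d_out, want_dx)
}

# ---- architectures ----------------------------------------------------------

# Encoder-decoder with three conv(3x3)+relu+pool stages, a dense bottleneck,
# and three stride-2 transposed-conv stages (relu, relu, sigmoid).
ae_layers <- function(input_px, channels, latent_dim) {
  p <- input_px
  stopifnot(p %% 8 == 0)
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  fm <- (p / 8)^2 * c3
  list(
    nn_layer("conv", h = p, w = p, cin = 3L, cout = c1),
    nn_layer("relu"),
    nn_layer("pool", h = p, w = p, cin = c1),
    nn_layer("conv", h = p / 2, w = p / 2, cin = c1, cout = c2),
    nn_layer("relu"),
    nn_layer("pool", h = p / 2, w = p / 2, cin = c2),
    nn_layer("conv", h = p / 4, w = p / 4, cin = c2, cout = c3),
    nn_layer("relu"),
    nn_layer("pool", h = p / 4, w = p / 4, cin = c3),
    nn_layer("dense", din = fm, dout = latent_dim),
    nn_layer("dense", din = latent_dim, dout = fm),
    nn_layer("relu"),
    nn_layer("tconv", h = p / 8, w = p / 8, cin = c3, cout = c2),
    nn_layer("relu"),
    nn_layer("tconv", h = p / 4, w = p / 4, cin = c2, cout = c1),
    nn_layer("relu"),
    nn_layer("tconv", h = p / 2, w = p / 2, cin = c1, cout = 3L),
    nn_layer("sigmoid")
  )
}

# WGAN generator: latent -> dense feature map -> three stride-2 upsampling
# stages ending in a sigmoid (pixel range [0,1]).
gan_generator_layers <- function(input_px, channels, latent_dim) {
  p <- input_px
  stopifnot(p %% 8 == 0)
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  fm <- (p / 8)^2 * c3
  list(
    nn_layer("dense", din = latent_dim, dout = fm),
    nn_layer("relu"),
    nn_layer("tconv", h = p / 8, w = p / 8, cin = c3, cout = c2),
    nn_layer("relu"),
    nn_layer("tconv", h = p / 4, w = p / 4, cin = c2, cout = c1),
    nn_layer("relu"),
    nn_layer("tconv", h = p / 2, w = p / 2, cin = c1, cout = 3L),
    nn_layer("sigmoid")
  )
}

# Critic/discriminator: conv+leaky-relu+pool stages, a dense feature layer
# (the izif feature map f(.) is taken after its activation, i.e. one layer
# before the final scalar output), then a scalar head.
gan_critic_layers <- function(input_px, channels, feature_dim) {
  p <- input_px
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  fm <- (p / 8)^2 * c3
  list(
    nn_layer("conv", h = p, w = p, cin = 3L, cout = c1),
    nn_layer("lrelu"),
    nn_layer("pool", h = p, w = p, cin = c1),
    nn_layer("conv", h = p / 2, w = p / 2, cin = c1, cout = c2),
    nn_layer("lrelu"),
    nn_layer("pool", h = p / 2, w = p / 2, cin = c2),
    nn_layer("conv", h = p / 4, w = p / 4, cin = c2, cout = c3),
    nn_layer("lrelu"),
    nn_layer("pool", h = p / 4, w = p / 4, cin = c3),
    nn_layer("dense", din = fm, dout = feature_dim),
    nn_layer("lrelu"),
    nn_layer("dense", din = feature_dim, dout = 1L)
  )
}

# Feature subnetwork f(.): the critic minus its final dense layer.  Because
# the parameter vector is laid out layer-by-layer, the feature net is
# parameterized by a prefix of the critic's parameter vector.
gan_feature_layers <- function(critic_layers) {
  critic_layers[seq_len(length(critic_layers) - 1L)]
}

# izif encoder: same downsampling trunk as the critic, ending at the latent.
gan_encoder_layers <- function(input_px, channels, latent_dim) {
  p <- input_px
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  fm <- (p / 8)^2 * c3
  list(
    nn_layer("conv", h = p, w = p, cin = 3L, cout = c1),
    nn_layer("relu"),
    nn_layer("pool", h = p, w = p, cin = c1),
    nn_layer("conv", h = p / 2, w = p / 2, cin = c1, cout = c2),
    nn_layer("relu"),
    nn_layer("pool", h = p / 2, w = p / 2, cin = c2),
    nn_layer("conv", h = p / 4, w = p / 4, cin = c2, cout = c3),
    nn_layer("relu"),
    nn_layer("pool", h = p / 4, w = p / 4, cin = c3),
    nn_layer("dense", din = fm, dout = latent_dim)
  )
}

# ---- optimizers -------------------------------------------------------------

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, params, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  params <- params - lr * mhat / (sqrt(vhat) + eps)
  list(state = state, params = params)
}

rmsprop_state <- function(n) list(v = numeric(n))

rmsprop_step <- function(state, params, grad, lr, rho = 0.9, eps = 1e-8) {
  state$v <- rho * state$v + (1 - rho) * grad^2
  params <- params - lr * grad / sqrt(state$v + eps)
  list(state = state, params = params)
}

make_optimizer <- function(name, n, lr) {
  name <- match.arg(name, c("adam", "rmsprop"))
  if (name == "adam") {
    st <- adam_state(n)
    function(params, grad) {
      res <- adam_step(st, params, grad, lr)
      st <<- res$state
      res$params
    }
  } else {
    st <- rmsprop_state(n)
    function(params, grad) {
      res <- rmsprop_step(st, params, grad, lr)
      st <<- res$state
      res$params
    }
  }
}

# Epoch index at which training stops when `losses` has shown no improvement
# over its running best for `patience` consecutive epochs; NA if it never
# stops within the sequence.
early_stop_epoch <- function(losses, patience) {
  stopifnot(patience >= 1)
  best <- Inf
  bad <- 0L
  for (i in seq_along(losses)) {
    if (losses[i] < best) {
      best <- losses[i]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(i)
    }
  }
  NA_integer_
}
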