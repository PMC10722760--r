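#' Deep sparse auto-encoder configuration
#'
#' A 4-layer sigmoid encoder and mirrored 4-layer sigmoid decoder compress
#' initial pair feature vectors into a bottleneck code (the "high-rank"
#' features). For the canonical 1311-wide input the layer widths are
#' 1311, 1152, 576, 288, 144 (decoder mirrored); for other input widths the
#' same compression profile is kept by scaling each hidden width
#' proportionally.
#'
#' @param input_dim width of the input vectors.
#' @param encoder_dims optional explicit widths (length 5, first =
#'   \code{input_dim}); decoder widths are always the reverse.
#' @param epochs training epochs (default 150).
#' @param learning_rate initial Adam learning rate (default 0.01).
#' @param kl_weight weight of the KL-divergence sparsity term (default 1).
#' @param kl_epsilon smoothing added before sum-normalization inside the KL
#'   term (default 1e-7).
#' @param lr_factor,lr_patience plateau schedule: multiply the learning rate
#'   by \code{lr_factor} when the loss has not improved for
#'   \code{lr_patience} epochs.
#' @param seed integer seed.
#' @return A list of class \code{mda_dae_config}.
#' @export
dae_config <- function(input_dim, encoder_dims = NULL, epochs = 150L,
                       learning_rate = 0.01, kl_weight = 1,
                       kl_epsilon = 1e-7, lr_factor = 0.5,
                       lr_patience = 10L, seed = 1L) {
  input_dim <- as.integer(input_dim)
  if (is.null(encoder_dims)) {
    ratios <- c(1152, 576, 288, 144) / 1311
    encoder_dims <- c(input_dim, pmax(1L, as.integer(round(input_dim * ratios))))
  }
  stopifnot(length(encoder_dims) == 5L, encoder_dims[1] == input_dim,
            all(encoder_dims >= 1L), epochs >= 1L, learning_rate > 0,
            kl_weight >= 0, kl_epsilon > 0)
  structure(list(input_dim = input_dim,
                 encoder_dims = as.integer(encoder_dims),
                 decoder_dims = rev(as.integer(encoder_dims)),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, kl_weight = kl_weight,
                 kl_epsilon = kl_epsilon, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 seed = as.integer(seed)),
            class = "mda_dae_config")
}

#' Initialize auto-encoder parameters (Glorot-uniform, seeded)
#'
#' @param cfg an [dae_config()].
#' @return Flat named list \code{We_k}, \code{be_k}, \code{Wd_t}, \code{bd_t}
#'   for k, t in 1..4, plus the config as attribute \code{"cfg"}.
#' @export
init_dae_params <- function(cfg) {
  set.seed(cfg$seed)
  e <- cfg$encoder_dims
  d <- cfg$decoder_dims
  params <- list()
  for (k in 1:4) {
    params[[paste0("We_", k)]] <- glorot_uniform(e[k], e[k + 1])
    params[[paste0("be_", k)]] <- numeric(e[k + 1])
  }
  for (t in 1:4) {
    params[[paste0("Wd_", t)]] <- glorot_uniform(d[t], d[t + 1])
    params[[paste0("bd_", t)]] <- numeric(d[t + 1])
  }
  attr(params, "cfg") <- cfg
  params
}

# forward with optional cache of activations; x is n x input_dim
.dae_forward_full <- function(params, x, cache = FALSE) {
  cfg <- attr(params, "cfg")
  x <- as.matrix(x)
  if (ncol(x) != cfg$input_dim)
    stop("input width ", ncol(x), " does not match encoder input ",
         cfg$input_dim)
  acts <- list(x)
  a <- x
  for (k in 1:4) {
    a <- sigmoid(add_rowvec(a %*% params[[paste0("We_", k)]],
                            params[[paste0("be_", k)]]))
    if (cache) acts[[length(acts) + 1L]] <- a
  }
  code <- a
  for (t in 1:4) {
    a <- sigmoid(add_rowvec(a %*% params[[paste0("Wd_", t)]],
                            params[[paste0("bd_", t)]]))
    if (cache) acts[[length(acts) + 1L]] <- a
  }
  list(code = code, recon = a, acts = if (cache) acts else NULL)
}

#' Auto-encoder forward pass
#'
#' @param params parameter list from [init_dae_params()] or [train_dae()].
#' @param x input matrix (rows = pairs) or a single vector.
#' @return List with \code{code} (bottleneck, sigmoid outputs) and
#'   \code{recon} (reconstruction).
#' @export
dae_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  out <- .dae_forward_full(params, x)
  out["acts"] <- NULL
  out
}

#' Auto-encoder loss: mean squared error plus KL sparsity term
#'
#' \code{MSE(x, x4) + theta * KL(xbar || x4bar)} where \code{xbar} and
#' \code{x4bar} are the epsilon-smoothed, sum-normalized row vectors. The KL
#' term is averaged over rows. Non-negative; zero exactly at perfect
#' reconstruction.
#'
#' @param x input matrix (entries in [0, 1]).
#' @param x4 reconstruction of the same shape.
#' @param theta KL weight.
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
dae_loss <- function(x, x4, theta = 1, eps = 1e-7) {
  x <- as.matrix(x); x4 <- as.matrix(x4)
  stopifnot(all(dim(x) == dim(x4)))
  mse <- mean((x - x4)^2)
  if (theta == 0) return(mse)
  xb <- (x + eps) / rowSums(x + eps)
  x4b <- (x4 + eps) / rowSums(x4 + eps)
  kl <- mean(rowSums(xb * log(xb / x4b)))
  mse + theta * kl
}

# loss and gradient wrt x4 (matching dae_loss exactly)
.dae_loss_grad <- function(x, x4, theta, eps) {
  n <- nrow(x); d <- ncol(x)
  mse <- mean((x - x4)^2)
  g <- 2 * (x4 - x) / (n * d)
  kl <- 0
  if (theta > 0) {
    sx <- rowSums(x + eps)
    s4 <- rowSums(x4 + eps)
    xb <- (x + eps) / sx
    x4b <- (x4 + eps) / s4
    kl <- mean(rowSums(xb * log(xb / x4b)))
    # d/dx4_j of row KL = -(xb_j / x4b_j - 1) / s4
    g <- g - theta * (xb / x4b - 1) / (s4 * n)
  }
  list(loss = mse + theta * kl, grad = g)
}

# full backward; returns flat gradient list
.dae_backward <- function(params, fwd, dRecon) {
  grads <- list()
  acts <- fwd$acts # acts[[1]] = x, [[2..5]] encoder, [[6..9]] decoder
  dA <- dRecon
  for (t in 4:1) {
    a <- acts[[5 + t]]
    dZ <- dA * a * (1 - a)
    inp <- acts[[4 + t]]
    grads[[paste0("Wd_", t)]] <- crossprod(inp, dZ)
    grads[[paste0("bd_", t)]] <- colSums(dZ)
    dA <- tcrossprod(dZ, params[[paste0("Wd_", t)]])
  }
  for (k in 4:1) {
    a <- acts[[1 + k]]
    dZ <- dA * a * (1 - a)
    inp <- acts[[k]]
    grads[[paste0("We_", k)]] <- crossprod(inp, dZ)
    grads[[paste0("be_", k)]] <- colSums(dZ)
    dA <- tcrossprod(dZ, params[[paste0("We_", k)]])
  }
  grads[names(params)]
}

#' Train the deep sparse auto-encoder
#'
#' Full-batch Adam on [dae_loss()] with a reduce-on-plateau learning-rate
#' schedule. Deterministic given \code{cfg$seed}.
#'
#' @param X input matrix of initial pair features (entries in [0, 1]).
#' @param cfg an [dae_config()]; defaults to \code{dae_config(ncol(X))}.
#' @return List of class \code{mda_dae_fit}: \code{params}, \code{losses},
#'   \code{cfg}.
#' @export
train_dae <- function(X, cfg = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty input matrix")
  if (is.null(cfg)) cfg <- dae_config(ncol(X))
  params <- init_dae_params(cfg)
  state <- adam_init(params)
  lr <- cfg$learning_rate
  best <- Inf
  stall <- 0L
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    fwd <- .dae_forward_full(params, X, cache = TRUE)
    lg <- .dae_loss_grad(X, fwd$recon, cfg$kl_weight, cfg$kl_epsilon)
    losses[ep] <- lg$loss
    grads <- .dae_backward(params, fwd, lg$grad)
    cfg_attr <- attr(params, "cfg")
    upd <- adam_step(state, params, grads, lr)
    state <- upd$state
    params <- upd$params
    attr(params, "cfg") <- cfg_attr
    if (lg$loss < best - 1e-8) {
      best <- lg$loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$lr_patience) {
        lr <- lr * cfg$lr_factor
        stall <- 0L
      }
    }
  }
  structure(list(params = params, losses = losses, cfg = cfg),
            class = "mda_dae_fit")
}

#' Encode pair features to the bottleneck code
#'
#' @param fit an \code{mda_dae_fit} (or a bare parameter list).
#' @param X matrix of input rows.
#' @return Matrix of codes, one row per input row.
#' @export
dae_encode <- function(fit, X) {
  params <- if (inherits(fit, "mda_dae_fit")) fit$params else fit
  dae_forward(params, X)$code
}
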