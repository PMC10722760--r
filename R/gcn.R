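#' Bipartite GCN encoder configuration
#'
#' A shallow (default two-layer) graph-convolutional encoder on the bipartite
#' association graph. Fused similarity matrices serve as initial node
#' features, projected to width \code{h1}; each graph-convolution layer mixes
#' degree-normalized neighbourhood aggregation with an element-wise local
#' structure term, ending at output width \code{h2}. Training minimizes a
#' binary cross-entropy reconstruction loss of the adjacency matrix.
#'
#' @param h1 projection / hidden width (default 256).
#' @param h2 embedding (output) width (default 128).
#' @param layers number of graph-convolution layers (default 2; widths are
#'   h1 -> h1 for all but the last layer, which maps h1 -> h2).
#' @param dropout dropout rate on inter-layer activations during training.
#' @param epochs training epochs (default 1000).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param seed integer seed (initialization and per-epoch negative draws).
#' @param resample_neg logical; resample the loss's negative pair set each
#'   epoch (default TRUE) or fix it once.
#' @param loss \code{"bce"} (default) uses the proper log(1 - yhat) negative
#'   term; \code{"one_minus_log"} uses the (1 - log yhat) variant for
#'   comparison.
#' @return A list of class \code{mda_gcn_config}.
#' @export
gcn_config <- function(h1 = 256L, h2 = 128L, layers = 2L, dropout = 0.5,
                       epochs = 1000L, learning_rate = 0.001, seed = 1L,
                       resample_neg = TRUE, loss = c("bce", "one_minus_log")) {
  stopifnot(layers >= 1L, h1 >= 1L, h2 >= 1L, dropout >= 0, dropout < 1,
            epochs >= 1L, learning_rate > 0)
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2),
                 layers = as.integer(layers), dropout = dropout,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), resample_neg = resample_neg,
                 loss = match.arg(loss)),
            class = "mda_gcn_config")
}

# per-layer (d_in, d_out) widths
.gcn_layer_dims <- function(cfg) {
  l <- cfg$layers
  ins <- rep(cfg$h1, l)
  outs <- c(rep(cfg$h1, l - 1L), cfg$h2)
  if (l == 1L) ins <- cfg$h1
  Map(function(a, b) c(a, b), ins, outs)
}

#' Initialize GCN parameters (Glorot-uniform, seeded)
#'
#' @param n_m,n_d numbers of microbes and diseases (initial feature widths).
#' @param cfg an [gcn_config()].
#' @return Flat named list of weight matrices and bias vectors.
#' @export
init_gcn_params <- function(n_m, n_d, cfg = gcn_config()) {
  set.seed(cfg$seed)
  params <- list(
    W0_M = glorot_uniform(n_m, cfg$h1),
    W0_D = glorot_uniform(n_d, cfg$h1),
    b_M = numeric(cfg$h1),
    b_D = numeric(cfg$h1)
  )
  dims <- .gcn_layer_dims(cfg)
  for (t in seq_len(cfg$layers)) {
    d <- dims[[t]]
    params[[paste0("W1_", t)]] <- glorot_uniform(d[1], d[2])
    params[[paste0("W2_", t)]] <- glorot_uniform(d[1], d[2])
    params[[paste0("b1_", t)]] <- numeric(d[2])
  }
  params
}

#' Degree-normalized bipartite adjacency
#'
#' \code{P = D1^(-1/2) Y D2^(-1/2)} with \code{D1 = diag(rowSums(Y) + 1)} and
#' \code{D2 = diag(colSums(Y) + 1)}; the +1 keeps the normalization defined
#' for isolated nodes.
#'
#' @param Y binary association matrix.
#' @return matrix of the same shape.
#' @export
normalized_adjacency <- function(Y) {
  Y <- as.matrix(Y)
  d1 <- rowSums(Y) + 1
  d2 <- colSums(Y) + 1
  Y / sqrt(outer(d1, d2))
}

# Forward pass. Returns embeddings and, when cache = TRUE, the intermediates
# needed by the backward pass. Dropout masks (inverted dropout) are applied
# to the ReLU outputs of all layers except the last, only when training.
.gcn_forward_full <- function(params, cfg, FuM, FuD, P, training = FALSE,
                              cache = FALSE) {
  HM <- add_rowvec(FuM %*% params$W0_M, params$b_M)
  HD <- add_rowvec(FuD %*% params$W0_D, params$b_D)
  layers <- vector("list", cfg$layers)
  for (t in seq_len(cfg$layers)) {
    W1 <- params[[paste0("W1_", t)]]
    W2 <- params[[paste0("W2_", t)]]
    b1 <- params[[paste0("b1_", t)]]
    AM <- P %*% HD
    AD <- crossprod(P, HM)
    SM <- AM * HM
    SD <- AD * HD
    ZM <- AM %*% W1 + add_rowvec(SM %*% W2, b1)
    ZD <- AD %*% W1 + add_rowvec(SD %*% W2, b1)
    outM <- pmax(ZM, 0)
    outD <- pmax(ZD, 0)
    maskM <- maskD <- NULL
    if (training && cfg$dropout > 0 && t < cfg$layers) {
      keep <- 1 - cfg$dropout
      maskM <- matrix(stats::rbinom(length(outM), 1, keep) / keep,
                      nrow(outM), ncol(outM))
      maskD <- matrix(stats::rbinom(length(outD), 1, keep) / keep,
                      nrow(outD), ncol(outD))
    }
    if (cache)
      layers[[t]] <- list(HM_in = HM, HD_in = HD, AM = AM, AD = AD,
                          SM = SM, SD = SD, ZM = ZM, ZD = ZD,
                          maskM = maskM, maskD = maskD)
    if (!is.null(maskM)) { outM <- outM * maskM; outD <- outD * maskD }
    HM <- outM
    HD <- outD
  }
  list(LM = HM, LD = HD, layers = if (cache) layers else NULL)
}

#' GCN forward pass
#'
#' Pure function of the parameters (no dropout): returns the low-rank
#' embeddings \code{LM} (microbes) and \code{LD} (diseases).
#'
#' @param params parameter list from [init_gcn_params()] or [train_gcn()].
#' @param cfg an [gcn_config()].
#' @param FuM,FuD fused similarity matrices (initial node features).
#' @param P normalized adjacency from [normalized_adjacency()].
#' @return List with matrices \code{LM} (n_m x h2) and \code{LD} (n_d x h2).
#' @export
gcn_forward <- function(params, cfg, FuM, FuD, P) {
  if (ncol(FuM) != nrow(params$W0_M) || ncol(FuD) != nrow(params$W0_D))
    stop("feature width does not match parameter shapes")
  out <- .gcn_forward_full(params, cfg, FuM, FuD, P)
  list(LM = out$LM, LD = out$LD)
}

#' Reconstruct the association matrix from embeddings
#'
#' \code{Yhat = logistic(LM . LD^T)}.
#'
#' @param emb list with \code{LM}, \code{LD} of equal width.
#' @return matrix of probabilities in (0, 1).
#' @export
gcn_reconstruct <- function(emb) {
  stopifnot(ncol(emb$LM) == ncol(emb$LD))
  sigmoid(tcrossprod(emb$LM, emb$LD))
}

# BCE (or one-minus-log) loss over the entries idx_pos (label 1) and idx_neg
# (label 0) of S = LM LD^T; n = number of positive edges.
.gcn_loss_grad <- function(LM, LD, idx_pos, idx_neg, loss_type) {
  S <- tcrossprod(LM, LD)
  yhat <- sigmoid(S)
  eps <- 1e-7
  yh <- pmin(pmax(yhat, eps), 1 - eps)
  n <- nrow(idx_pos)
  yp <- yh[idx_pos]
  yn <- yh[idx_neg]
  if (loss_type == "bce") {
    loss <- -(sum(log(yp)) + sum(log(1 - yn))) / n
  } else {
    loss <- -(sum(log(yp)) + sum(1 - log(yn))) / n
  }
  G <- matrix(0, nrow(S), ncol(S))
  G[idx_pos] <- G[idx_pos] - (1 - yp) / n
  if (loss_type == "bce") {
    G[idx_neg] <- G[idx_neg] + yn / n
  } else {
    G[idx_neg] <- G[idx_neg] + (1 - yn) / n
  }
  list(loss = loss, dLM = G %*% LD, dLD = crossprod(G, LM))
}

# Backward pass through the cached forward; returns gradients for all params.
.gcn_backward <- function(params, cfg, FuM, FuD, P, fwd, dLM, dLD) {
  grads <- lapply(params, function(p) p * 0)
  dHM <- dLM
  dHD <- dLD
  for (t in rev(seq_len(cfg$layers))) {
    lc <- fwd$layers[[t]]
    if (!is.null(lc$maskM)) { dHM <- dHM * lc$maskM; dHD <- dHD * lc$maskD }
    dZM <- dHM * (lc$ZM > 0)
    dZD <- dHD * (lc$ZD > 0)
    W1 <- params[[paste0("W1_", t)]]
    W2 <- params[[paste0("W2_", t)]]
    grads[[paste0("W1_", t)]] <- crossprod(lc$AM, dZM) + crossprod(lc$AD, dZD)
    grads[[paste0("W2_", t)]] <- crossprod(lc$SM, dZM) + crossprod(lc$SD, dZD)
    grads[[paste0("b1_", t)]] <- colSums(dZM) + colSums(dZD)
    dAM <- tcrossprod(dZM, W1)
    dAD <- tcrossprod(dZD, W1)
    dSM <- tcrossprod(dZM, W2)
    dSD <- tcrossprod(dZD, W2)
    dAM <- dAM + dSM * lc$HM_in
    dAD <- dAD + dSD * lc$HD_in
    dHM_in <- dSM * lc$AM
    dHD_in <- dSD * lc$AD
    dHD_in <- dHD_in + crossprod(P, dAM)
    dHM_in <- dHM_in + P %*% dAD
    dHM <- dHM_in
    dHD <- dHD_in
  }
  grads$W0_M <- crossprod(FuM, dHM)
  grads$b_M <- colSums(dHM)
  grads$W0_D <- crossprod(FuD, dHD)
  grads$b_D <- colSums(dHD)
  grads
}

#' Train the bipartite GCN encoder
#'
#' Minimizes the reconstruction binary cross-entropy over the positive edges
#' plus an equal number of sampled non-edges (resampled uniformly each epoch
#' by default), with full-batch Adam. Deterministic given \code{cfg$seed}.
#'
#' @param net an \code{mda_network} (must have at least one edge).
#' @param FuM,FuD fused similarity matrices.
#' @param cfg an [gcn_config()].
#' @return List of class \code{mda_gcn_fit}: \code{LM}, \code{LD} (embeddings
#'   from a dropout-free forward pass), \code{params}, \code{losses}
#'   (per-epoch), \code{cfg}.
#' @export
train_gcn <- function(net, FuM, FuD, cfg = gcn_config()) {
  stopifnot(inherits(net, "mda_network"))
  Y <- net$Y
  idx_pos <- which(Y == 1, arr.ind = TRUE)
  if (nrow(idx_pos) == 0L) stop("network has no edges; cannot train")
  zeros <- which(Y == 0, arr.ind = TRUE)
  if (nrow(zeros) < nrow(idx_pos))
    stop("not enough non-edges to sample a negative set of size |E|")
  P <- normalized_adjacency(Y)
  params <- init_gcn_params(nrow(Y), ncol(Y), cfg)
  state <- adam_init(params)
  losses <- numeric(cfg$epochs)
  n_pos <- nrow(idx_pos)
  idx_neg <- zeros[sample.int(nrow(zeros), n_pos), , drop = FALSE]
  for (ep in seq_len(cfg$epochs)) {
    if (cfg$resample_neg && ep > 1L)
      idx_neg <- zeros[sample.int(nrow(zeros), n_pos), , drop = FALSE]
    fwd <- .gcn_forward_full(params, cfg, FuM, FuD, P, training = TRUE,
                             cache = TRUE)
    lg <- .gcn_loss_grad(fwd$LM, fwd$LD, idx_pos, idx_neg, cfg$loss)
    losses[ep] <- lg$loss
    grads <- .gcn_backward(params, cfg, FuM, FuD, P, fwd, lg$dLM, lg$dLD)
    upd <- adam_step(state, params, grads, cfg$learning_rate)
    state <- upd$state
    params <- upd$params
  }
  emb <- gcn_forward(params, cfg, FuM, FuD, P)
  structure(list(LM = emb$LM, LD = emb$LD, params = params, losses = losses,
                 cfg = cfg),
            class = "mda_gcn_fit")
}
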