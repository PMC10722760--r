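test_that("normalized adjacency equals the per-entry closed form", {
  expect_equal(normalized_adjacency(rbind(c(1, 0), c(0, 0))),
               rbind(c(0.5, 0), c(0, 0)))
  expect_equal(normalized_adjacency(matrix(1, 1, 1)), matrix(0.5, 1, 1))
  expect_true(all(normalized_adjacency(matrix(0, 3, 2)) == 0))
  for (seed in 1:20) {
    set.seed(seed)
    Y <- matrix(rbinom(30, 1, 0.4), 6, 5)
    P <- normalized_adjacency(Y)
    rs <- rowSums(Y); cs <- colSums(Y)
    for (i in 1:6) for (j in 1:5)
      expect_identical(P[i, j], Y[i, j] / sqrt((rs[i] + 1) * (cs[j] + 1)))
    expect_true(all(P >= 0 & P < 1))
  }
})

test_that("forward pass matches the hand-computed single-node scalar chain", {
  # N_m = N_d = 1, h1 = h2 = 1, all weights 1, biases 0, Y = FuM = FuD = [[1]]
  cfg <- gcn_config(h1 = 1, h2 = 1, layers = 2, dropout = 0, epochs = 1,
                    seed = 1)
  params <- init_gcn_params(1, 1, cfg)
  for (nm in names(params)) params[[nm]][] <- if (grepl("^b", nm)) 0 else 1
  P <- normalized_adjacency(matrix(1, 1, 1)) # 0.5
  emb <- gcn_forward(params, cfg, matrix(1, 1, 1), matrix(1, 1, 1), P)
  # per layer: A = 0.5*H, N = 0.5*H, G = 0.5*H*H; H' = relu(0.5H + 0.5H^2)
  h1 <- 0.5 * 1 + 0.5 * 1   # = 1
  h2 <- 0.5 * h1 + 0.5 * h1^2
  expect_equal(emb$LM[1, 1], h2)
  expect_equal(emb$LD[1, 1], h2)
  expect_equal(gcn_reconstruct(emb)[1, 1], 1 / (1 + exp(-h2^2)))
})

test_that("zero parameters yield zero embeddings and 0.5 reconstructions", {
  cfg <- gcn_config(h1 = 3, h2 = 2, dropout = 0, epochs = 1, seed = 1)
  params <- init_gcn_params(4, 3, cfg)
  for (nm in names(params)) params[[nm]][] <- 0
  net <- random_net(4, 3, 0.4, 2)
  FuM <- diag(1, 4); FuD <- diag(1, 3)
  emb <- gcn_forward(params, cfg, FuM, FuD, normalized_adjacency(net$Y))
  expect_true(all(emb$LM == 0) && all(emb$LD == 0))
  expect_true(all(gcn_reconstruct(emb) == 0.5))
  expect_equal(dim(emb$LM), c(4L, 2L))
  big <- gcn_reconstruct(list(LM = matrix(10, 1, 1), LD = matrix(10, 1, 1)))
  expect_equal(big[1, 1], 1 / (1 + exp(-100)))
})

test_that("analytic gradients match finite differences on a small instance", {
  set.seed(5)
  n_m <- 4; n_d <- 3
  cfg <- gcn_config(h1 = 3, h2 = 2, dropout = 0, epochs = 1, seed = 5)
  params <- init_gcn_params(n_m, n_d, cfg)
  # move biases off zero so no pre-activation sits exactly on the ReLU kink
  # (isolated nodes otherwise give Z = 0, where FD and subgradient differ)
  for (nm in grep("^b", names(params), value = TRUE)) params[[nm]][] <- 0.05
  Y <- matrix(rbinom(n_m * n_d, 1, 0.5), n_m, n_d)
  Y[1, 1] <- 1; Y[2, 2] <- 0
  FuM <- matrix(runif(n_m^2), n_m); FuM <- (FuM + t(FuM)) / 2
  FuD <- matrix(runif(n_d^2), n_d); FuD <- (FuD + t(FuD)) / 2
  P <- normalized_adjacency(Y)
  idx_pos <- which(Y == 1, arr.ind = TRUE)
  idx_neg <- which(Y == 0, arr.ind = TRUE)
  loss_of <- function(pp) {
    f <- mdapred:::.gcn_forward_full(pp, cfg, FuM, FuD, P)
    mdapred:::.gcn_loss_grad(f$LM, f$LD, idx_pos, idx_neg, "bce")$loss
  }
  fwd <- mdapred:::.gcn_forward_full(params, cfg, FuM, FuD, P, cache = TRUE)
  lg <- mdapred:::.gcn_loss_grad(fwd$LM, fwd$LD, idx_pos, idx_neg, "bce")
  grads <- mdapred:::.gcn_backward(params, cfg, FuM, FuD, P, fwd,
                                   lg$dLM, lg$dLD)
  h <- 1e-6
  for (nm in names(params)) {
    picks <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in picks) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + h
      up <- loss_of(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      dn <- loss_of(pp)
      fd <- (up - dn) / (2 * h)
      expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("forward pass is permutation-equivariant in the microbes", {
  set.seed(6)
  n_m <- 6; n_d <- 4
  cfg <- gcn_config(h1 = 4, h2 = 3, dropout = 0, epochs = 1, seed = 6)
  params <- init_gcn_params(n_m, n_d, cfg)
  Y <- matrix(rbinom(n_m * n_d, 1, 0.4), n_m, n_d)
  FuM <- crossprod(matrix(runif(n_m^2), n_m)); FuM <- FuM / max(FuM)
  FuD <- crossprod(matrix(runif(n_d^2), n_d)); FuD <- FuD / max(FuD)
  emb <- gcn_forward(params, cfg, FuM, FuD, normalized_adjacency(Y))
  perm <- sample(n_m)
  params_p <- params
  params_p$W0_M <- params$W0_M[perm, , drop = FALSE]
  emb_p <- gcn_forward(params_p, cfg, FuM[perm, perm], FuD,
                       normalized_adjacency(Y[perm, ]))
  expect_equal(emb_p$LM, emb$LM[perm, , drop = FALSE], tolerance = 1e-12)
  expect_equal(emb_p$LD, emb$LD, tolerance = 1e-12)
})

test_that("training reduces the loss, separates planted edges, and is seed-deterministic", {
  bench <- small_benchmark()
  b <- build_similarity_bundle(bench$net, bench$dag)
  cfg <- gcn_config(h1 = 16, h2 = 8, epochs = 150, seed = 3)
  fit <- train_gcn(bench$net, b$FuM, b$FuD, cfg)
  expect_true(all(is.finite(fit$losses)))
  expect_lt(tail(fit$losses, 1), fit$losses[1])
  # 50-epoch moving average non-increasing (smoke, with tolerance)
  ma <- stats::filter(fit$losses, rep(1 / 50, 50), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) < 0.01))
  Yhat <- gcn_reconstruct(fit)
  expect_gt(mean(Yhat[bench$net$Y == 1]), mean(Yhat[bench$net$Y == 0]))
  expect_true(all(fit$LM >= 0) && all(fit$LD >= 0)) # rectified outputs
  fit2 <- train_gcn(bench$net, b$FuM, b$FuD, cfg)
  expect_identical(fit$LM, fit2$LM)
  empty <- association_network("m", "d", matrix(0, 1, 1))
  expect_error(train_gcn(empty, matrix(1, 1, 1), matrix(1, 1, 1), cfg),
               "no edges")
})

test_that("dropout-free forward pass is bitwise repeatable", {
  set.seed(8)
  cfg <- gcn_config(h1 = 4, h2 = 2, dropout = 0.5, epochs = 1, seed = 8)
  params <- init_gcn_params(5, 3, cfg)
  Y <- matrix(rbinom(15, 1, 0.4), 5, 3)
  FuM <- diag(1, 5); FuD <- diag(1, 3)
  P <- normalized_adjacency(Y)
  a <- gcn_forward(params, cfg, FuM, FuD, P)
  b <- gcn_forward(params, cfg, FuM, FuD, P)
  expect_identical(a, b)
})
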