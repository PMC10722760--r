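test_that("encoder dims reproduce the canonical layer list and scale proportionally", {
  cfg <- dae_config(1311)
  expect_equal(cfg$encoder_dims, c(1311L, 1152L, 576L, 288L, 144L))
  expect_equal(cfg$decoder_dims, rev(cfg$encoder_dims))
  cfg2 <- dae_config(240)
  expect_equal(cfg2$encoder_dims[1], 240L)
  expect_equal(cfg2$encoder_dims[5], round(240 * 144 / 1311))
  params <- init_dae_params(dae_config(20, seed = 4))
  out <- dae_forward(params, matrix(runif(60), 3, 20))
  expect_equal(ncol(out$code), round(20 * 144 / 1311))
  expect_equal(dim(out$recon), c(3L, 20L))
})

test_that("zero parameters give all-0.5 activations and width mismatches error", {
  cfg <- dae_config(10, seed = 1)
  params <- init_dae_params(cfg)
  for (nm in names(params)) params[[nm]][] <- 0
  attr(params, "cfg") <- cfg
  out <- dae_forward(params, matrix(runif(20), 2, 10))
  expect_true(all(out$code == 0.5))
  expect_true(all(out$recon == 0.5))
  expect_error(dae_forward(params, matrix(0, 2, 7)), "width")
})

test_that("forward pass matches a hand-computed scalar sigmoid chain", {
  cfg <- dae_config(1, encoder_dims = c(1L, 1L, 1L, 1L, 1L), seed = 1)
  params <- init_dae_params(cfg)
  w <- c(0.5, -1, 2, 0.3, 1.5, -0.7, 0.2, 1)
  bs <- c(0.1, -0.2, 0.3, 0, -0.1, 0.2, 0, 0.05)
  sig <- function(x) 1 / (1 + exp(-x))
  nms <- c(paste0("We_", 1:4), paste0("Wd_", 1:4))
  bnms <- c(paste0("be_", 1:4), paste0("bd_", 1:4))
  for (i in 1:8) {
    params[[nms[i]]][] <- w[i]
    params[[bnms[i]]][] <- bs[i]
  }
  attr(params, "cfg") <- cfg
  a <- 0.7
  for (i in 1:8) a <- sig(w[i] * a + bs[i])
  out <- dae_forward(params, matrix(0.7, 1, 1))
  expect_equal(out$recon[1, 1], a)
})

test_that("loss is non-negative, zero only at perfect reconstruction, and matches hand values", {
  expect_equal(dae_loss(matrix(0.3, 2, 4), matrix(0.3, 2, 4)), 0)
  x <- matrix(c(1, 0), 1, 2)
  x4 <- matrix(0.5, 1, 2)
  expect_equal(dae_loss(x, x4, theta = 0), 0.25)
  expect_equal(dae_loss(x, x4, theta = 1, eps = 1e-12), 0.25 + log(2),
               tolerance = 1e-6)
  for (seed in 1:25) {
    set.seed(seed)
    a <- matrix(runif(12), 3, 4)
    b <- matrix(runif(12), 3, 4)
    expect_gte(dae_loss(a, b), 0)
    expect_gt(dae_loss(a, b), 0) # distinct random matrices
    expect_equal(dae_loss(a, a), 0)
  }
})

test_that("analytic loss-and-network gradient matches finite differences on a 5-d toy", {
  cfg <- dae_config(5, encoder_dims = c(5L, 4L, 3L, 2L, 2L), seed = 7,
                    kl_weight = 1)
  params <- init_dae_params(cfg)
  set.seed(7)
  X <- matrix(runif(15), 3, 5)
  loss_of <- function(pp) {
    attr(pp, "cfg") <- cfg
    f <- mdapred:::.dae_forward_full(pp, X)
    dae_loss(X, f$recon, cfg$kl_weight, cfg$kl_epsilon)
  }
  fwd <- mdapred:::.dae_forward_full(params, X, cache = TRUE)
  lg <- mdapred:::.dae_loss_grad(X, fwd$recon, cfg$kl_weight, cfg$kl_epsilon)
  expect_equal(lg$loss, dae_loss(X, fwd$recon, cfg$kl_weight, cfg$kl_epsilon))
  grads <- mdapred:::.dae_backward(params, fwd, lg$grad)
  h <- 1e-6
  for (nm in names(params)) {
    picks <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in picks) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + h
      up <- loss_of(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      dn <- loss_of(pp)
      expect_equal(grads[[nm]][i], (up - dn) / (2 * h), tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("training reduces loss, memorizes constant data, and is seed-deterministic", {
  set.seed(2)
  X <- matrix(runif(40 * 12), 40, 12)
  cfg <- dae_config(12, epochs = 80, seed = 2)
  fit <- train_dae(X, cfg)
  expect_lt(tail(fit$losses, 1), fit$losses[1])
  fit2 <- train_dae(X, cfg)
  expect_identical(fit$params, fit2$params)

  Xc <- matrix(rep(runif(12), each = 30), 30, 12)
  fitc <- train_dae(Xc, dae_config(12, epochs = 300, seed = 3))
  rec <- dae_forward(fitc$params, Xc)$recon
  expect_lt(mean((Xc - rec)^2), 1e-3)
  expect_error(train_dae(matrix(0, 0, 5)), "empty")
})

test_that("encoding is a pure row-wise function with outputs in (0,1)", {
  set.seed(4)
  X <- matrix(runif(10 * 8), 10, 8)
  fit <- train_dae(X, dae_config(8, epochs = 30, seed = 4))
  Z <- dae_encode(fit, X)
  expect_equal(nrow(Z), 10)
  expect_true(all(Z > 0 & Z < 1))
  expect_identical(Z, dae_encode(fit, X))
  X2 <- X[c(1, 1, 3), ]
  Z2 <- dae_encode(fit, X2)
  expect_identical(Z2[1, ], Z2[2, ])
})
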