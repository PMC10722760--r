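test_that("semantic contributions match hand-derived values on chain, singleton and diamond", {
  dag <- chain_dag()
  expect_equal(semantic_contributions(dag, "C"), c(C = 1, B = 0.5, A = 0.25))
  iso <- disease_ontology("solo")
  expect_equal(semantic_contributions(iso, "solo"), c(solo = 1))
  diamond <- disease_ontology(c("A", "B", "C", "D"),
                              list(D = c("B", "C"), B = "A", C = "A"))
  sc <- semantic_contributions(diamond, "D")
  expect_equal(sc[["A"]], 0.25)
  expect_error(semantic_contributions(dag, "nope"), "unknown term")
})

test_that("semantic value sums contributions and rejects empty maps", {
  expect_equal(semantic_value(c(C = 1, B = 0.5, A = 0.25)), 1.75)
  expect_equal(semantic_value(c(d = 1)), 1)
  expect_error(semantic_value(numeric()), "empty")
})

test_that("semantic contributions equal the brute-force path-enumeration oracle", {
  for (seed in 1:60) {
    n <- sample(2:12, 1)
    dag <- random_small_dag(n, 0.35, seed)
    for (d in dag$terms) {
      got <- semantic_contributions(dag, d, 0.5)
      want <- oracle_semantic_contributions(dag, d, 0.5)
      expect_identical(got[order(names(got))], want[order(names(want))],
                       info = sprintf("seed %d, term %s", seed, d))
    }
  }
})

test_that("disease semantic similarity matches hand evaluation and handles fallbacks", {
  dag <- chain_dag()
  DS <- disease_semantic_similarity(dag, c("B", "C"))
  expect_equal(DS["B", "C"], 2.25 / 3.25)
  expect_equal(diag(DS), c(B = 1, C = 1))
  # disjoint roots share no ancestors
  dag2 <- disease_ontology(c("r1", "r2", "x", "y"), list(x = "r1", y = "r2"))
  DS2 <- disease_semantic_similarity(dag2, c("r1", "r2"))
  expect_equal(DS2["r1", "r2"], 0)
  # diseases absent from the DAG: zero off-diagonal, unit diagonal
  DS3 <- disease_semantic_similarity(dag, c("B", "unknown"))
  expect_equal(DS3["B", "unknown"], 0)
  expect_equal(DS3["unknown", "unknown"], 1)
})

test_that("semantic similarity responds to FC as the closed form predicts", {
  # FC monotonicity is not a global property: for a descendant-ancestor pair
  # whose private ancestors sit closer than the shared ones, DS decreases in
  # FC (e.g. DS = (1 + f^3) / (2 + f + f^2 + f^3) on a 4-chain). The closed
  # forms below pin the implementation on both regimes.
  dag <- chain_dag()
  for (f in c(0.2, 0.5, 0.8)) {
    DS <- disease_semantic_similarity(dag, c("B", "C"),
                                      similarity_config(FC = f))
    expect_equal(DS["B", "C"], (1 + 2 * f + f^2) / (2 + 2 * f + f^2))
  }
  chain4 <- disease_ontology(c("A", "B", "C", "D"),
                             list(D = "C", C = "B", B = "A"))
  for (f in c(0.2, 0.5, 0.8)) {
    DS <- disease_semantic_similarity(chain4, c("D", "A"),
                                      similarity_config(FC = f))
    expect_equal(DS["D", "A"], (1 + f^3) / (2 + f + f^2 + f^3))
  }
  # sibling-pair similarity (shared parent one step away) increases with FC
  sib <- disease_ontology(c("P", "x", "y"), list(x = "P", y = "P"))
  vals <- vapply(c(0.2, 0.5, 0.8), function(f)
    disease_semantic_similarity(sib, c("x", "y"),
                                similarity_config(FC = f))["x", "y"],
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("GIP kernel matches hand evaluation, has unit diagonal, errors on zero profiles", {
  g <- gip_similarity(rbind(c(1, 0), c(0, 1)), alpha = 1)
  expect_equal(g$gamma, 1)
  expect_equal(g$K[1, 2], exp(-2))
  expect_equal(diag(g$K), c(1, 1))
  expect_error(gip_similarity(matrix(0, 3, 2)), "degenerate")
})

test_that("GIP kernel is permutation-equivariant", {
  set.seed(42)
  P <- matrix(rbinom(40, 1, 0.4), 8, 5)
  P[1, 1] <- 1 # guard against an all-zero matrix
  K <- gip_similarity(P)$K
  perm <- sample(8)
  Kp <- gip_similarity(P[perm, ])$K
  expect_equal(Kp, K[perm, perm], tolerance = 1e-12)
})

test_that("cosine and sigmoid kernels match hand values and conventions", {
  expect_equal(cosine_profile_similarity(rbind(c(1, 0), c(0, 1)))[1, 2], 0)
  expect_equal(cosine_profile_similarity(rbind(c(1, 1), c(1, 0)))[1, 2],
               1 / sqrt(2))
  Kz <- cosine_profile_similarity(rbind(c(0, 0), c(1, 0)))
  expect_equal(Kz[1, 2], 0)
  expect_equal(Kz[1, 1], 0) # zero-profile diagonal stays 0 by convention
  expect_equal(sigmoid_kernel_similarity(rbind(rep(1, 4), rep(1, 4)), 4)[1, 2],
               tanh(1))
  expect_equal(sigmoid_kernel_similarity(matrix(0, 2, 3), 5)[1, 2], 0)
  expect_error(sigmoid_kernel_similarity(matrix(1, 2, 2), 0), "norm")
})

test_that("microbe functional similarity matches hand evaluation of the best-match formula", {
  net <- association_network(c("i", "j"), "d", matrix(1, 2, 1))
  expect_equal(microbe_functional_similarity(net, matrix(1, 1, 1))[1, 2], 1)

  net2 <- association_network(c("i", "j"), c("d1", "d2", "d3"),
                              rbind(c(1, 0, 0), c(0, 1, 1)))
  DS <- diag(1, 3)
  DS[1, 2] <- DS[2, 1] <- 0.6
  DS[1, 3] <- DS[3, 1] <- 0.2
  expect_equal(microbe_functional_similarity(net2, DS)[1, 2],
               (0.6 + 0.6 + 0.2) / 3)
  # disjoint disease sets with zero cross-similarity
  DS0 <- diag(1, 3)
  expect_equal(microbe_functional_similarity(net2, DS0)[1, 2], 0)
  # isolated microbe: zero off-diagonal, unit diagonal
  net3 <- association_network(c("i", "j"), "d", rbind(1, 0))
  F3 <- microbe_functional_similarity(net3, matrix(1, 1, 1))
  expect_equal(F3[1, 2], 0)
  expect_equal(diag(F3), c(i = 1, j = 1))
})

test_that("fusion is the element-wise mean of exactly four matrices", {
  M <- matrix(runif(9), 3, 3)
  expect_equal(fuse_kernels(list(M, M, M, M)), M)
  a <- matrix(1, 2, 2); b <- matrix(2, 2, 2)
  c_ <- matrix(3, 2, 2); d <- matrix(6, 2, 2)
  expect_equal(fuse_kernels(list(a, b, c_, d)), matrix(3, 2, 2))
  expect_error(fuse_kernels(list(a, b, c_)), "exactly 4")
  expect_error(fuse_kernels(list(a, b, c_, matrix(0, 3, 3))), "identical shape")
})

test_that("all eight kernels and fused matrices are symmetric with entries in [0,1] and contracted diagonals", {
  for (seed in 1:50) {
    net <- random_net(sample(4:12, 1), sample(3:8, 1), 0.3, seed)
    dag <- random_small_dag(length(net$disease_ids), 0.4, seed)
    # map network diseases onto DAG terms
    dag$terms <- net$disease_ids
    names(dag$child_to_parents) <-
      net$disease_ids[match(names(dag$child_to_parents),
                            sprintf("t%d", seq_along(net$disease_ids)))]
    dag$child_to_parents <- lapply(dag$child_to_parents, function(p)
      net$disease_ids[match(p, sprintf("t%d", seq_along(net$disease_ids)))])
    b <- build_similarity_bundle(net, dag)
    for (nm in c("DS", "GDS", "CDS", "SDS", "FMS", "GMS", "CMS", "SMS",
                 "FuD", "FuM")) {
      M <- b[[nm]]
      expect_lt(max(abs(M - t(M))), 1e-12)
      expect_true(all(M >= 0 & M <= 1), info = paste(nm, "seed", seed))
    }
    expect_equal(unname(diag(b$DS)), rep(1, ncol(net$Y)))
    expect_equal(unname(diag(b$GDS)), rep(1, ncol(net$Y)))
    expect_equal(unname(diag(b$GMS)), rep(1, nrow(net$Y)))
    expect_equal(unname(diag(b$FMS)), rep(1, nrow(net$Y)))
    # cosine diagonal is 1 exactly for nonzero profiles, else 0
    dz <- colSums(net$Y) == 0
    expect_equal(unname(diag(b$CDS)), as.numeric(!dz))
  }
})

test_that("masking positives before kernel computation is equivalent to computing on the masked network", {
  net <- random_net(10, 6, 0.3, 7)
  pos <- which(net$Y == 1, arr.ind = TRUE)
  mask <- pos[1:2, , drop = FALSE]
  b_masked <- build_similarity_bundle(net, NULL, mask_pairs = mask)
  Y2 <- net$Y; Y2[mask] <- 0
  net2 <- association_network(net$microbe_ids, net$disease_ids, Y2)
  b2 <- build_similarity_bundle(net2, NULL)
  expect_equal(b_masked$FuM, b2$FuM)
  expect_equal(b_masked$FuD, b2$FuD)
  # empty mask is the unmasked call
  b0 <- build_similarity_bundle(net, NULL)
  b_empty <- build_similarity_bundle(net, NULL,
                                     mask_pairs = matrix(0L, 0, 2))
  expect_equal(b_empty$FuD, b0$FuD)
  # masking every positive degenerates the GIP bandwidth
  expect_error(build_similarity_bundle(net, NULL, mask_pairs = pos),
               "degenerate")
})

test_that("bundle export writes ten TSV matrices plus a manifest", {
  net <- random_net(6, 4, 0.3, 3)
  b <- build_similarity_bundle(net, NULL)
  dir <- withr::local_tempdir()
  write_similarity_bundle(b, dir)
  expect_length(list.files(dir, pattern = "\\.tsv$"), 10)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$gamma_d, b$gamma_d)
  back <- read_matrix_tsv(file.path(dir, "FuD.tsv"))
  expect_equal(back, b$FuD, tolerance = 1e-12)
})
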