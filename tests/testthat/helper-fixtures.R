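# Shared fixtures, built in code.

# tiny hand-constructed network: Y = [[1,0],[1,1]]
tiny_net <- function() {
  association_network(c("m1", "m2"), c("d1", "d2"),
                      rbind(c(1, 0), c(1, 1)))
}

# 3-term chain ontology: C is_a B is_a A
chain_dag <- function() {
  disease_ontology(c("A", "B", "C"), list(C = "B", B = "A"))
}

# random sparse network for property tests
random_net <- function(n_m, n_d, density = 0.15, seed = 1) {
  set.seed(seed)
  repeat {
    Y <- matrix(rbinom(n_m * n_d, 1, density), n_m, n_d)
    if (sum(Y) > 0) break
  }
  association_network(sprintf("m%d", seq_len(n_m)),
                      sprintf("d%d", seq_len(n_d)), Y)
}

# random DAG over <= n terms via a random topological order (edges only from
# later to earlier terms), for oracle comparisons
random_small_dag <- function(n_terms, p_edge = 0.35, seed = 1) {
  set.seed(seed)
  terms <- sprintf("t%d", seq_len(n_terms))
  c2p <- list()
  for (i in seq_len(n_terms)) {
    if (i == 1L) next
    parents <- terms[seq_len(i - 1L)][runif(i - 1L) < p_edge]
    if (length(parents) > 0L) c2p[[terms[i]]] <- parents
  }
  disease_ontology(terms, c2p)
}

# brute-force semantic-contribution oracle: enumerate every directed path
# from d upward; contribution of an ancestor = max over paths of FC^length
oracle_semantic_contributions <- function(dag, d, FC = 0.5) {
  out <- stats::setNames(1, d)
  walk <- function(node, depth) {
    for (p in dag$child_to_parents[[node]]) {
      v <- FC^(depth + 1L)
      if (is.na(out[p]) || v > out[[p]]) out[p] <<- v
      walk(p, depth + 1L)
    }
  }
  walk(d, 0L)
  out
}

# small planted-block benchmark for fast training tests
small_benchmark <- function(seed = 13) {
  make_benchmark(synthetic_spec(n_microbes = 60, n_diseases = 16,
                                n_blocks = 2, p_in = 0.4, p_out = 0.02,
                                seed = seed))
}

# the reference desk-scale benchmark (fixed study conditions)
reference_benchmark <- function() {
  make_benchmark(synthetic_spec(n_microbes = 200, n_diseases = 40,
                                n_blocks = 4, p_in = 0.3, p_out = 0.01,
                                seed = 13))
}

# benchmark-scale stage configurations used by the heavier evaluation tests:
# GCN capacity scaled to the 240-node graph, epochs at the loss plateau
bench_gcn_cfg <- function(seed = 1) {
  gcn_config(h1 = 64, h2 = 32, epochs = 300, seed = seed)
}
bench_dae_opts <- function(seed = 1) list(epochs = 150, seed = seed)
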