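#' Specification for a planted-block synthetic benchmark
#'
#' Emulates the statistical regime of curated microbe-disease association
#' catalogues: a sparse bipartite network (a few percent density) with
#' co-cluster structure and strongly imbalanced node-set sizes.
#'
#' @param n_microbes,n_diseases node-set sizes (defaults 200 and 40, keeping
#'   a several-fold microbe/disease imbalance at desk scale).
#' @param n_blocks number of planted (microbe-block, disease-block) pairings.
#' @param p_in edge probability inside a planted pairing.
#' @param p_out background edge probability.
#' @param dag_depth,dag_branching layered random ontology parameters.
#' @param min_degree if 1, isolated nodes are repaired with one random edge.
#' @param seed integer seed.
#' @return A list of class \code{mda_synthetic_spec}.
#' @export
synthetic_spec <- function(n_microbes = 200L, n_diseases = 40L, n_blocks = 4L,
                           p_in = 0.3, p_out = 0.01, dag_depth = 3L,
                           dag_branching = 2L, min_degree = 0L, seed = 13L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            n_blocks >= 1L, n_blocks <= min(n_microbes, n_diseases),
            dag_depth >= 1L)
  structure(list(n_microbes = as.integer(n_microbes),
                 n_diseases = as.integer(n_diseases),
                 n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
                 dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 min_degree = as.integer(min_degree),
                 seed = as.integer(seed)),
            class = "mda_synthetic_spec")
}

#' Generate a planted-block bipartite association network
#'
#' Microbes and diseases are assigned uniformly to blocks; an edge appears
#' with probability \code{p_in} when the two blocks are paired and
#' \code{p_out} otherwise.
#'
#' @param spec an [synthetic_spec()].
#' @return List with \code{net} (an \code{mda_network}) and the block
#'   assignments \code{microbe_block}, \code{disease_block}.
#' @export
generate_block_bipartite <- function(spec) {
  set.seed(spec$seed)
  mb <- sample(rep(seq_len(spec$n_blocks), length.out = spec$n_microbes))
  db <- sample(rep(seq_len(spec$n_blocks), length.out = spec$n_diseases))
  paired <- outer(mb, db, "==")
  p <- ifelse(paired, spec$p_in, spec$p_out)
  Y <- matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p))
  if (spec$min_degree >= 1L) {
    for (i in which(rowSums(Y) == 0)) Y[i, sample.int(ncol(Y), 1)] <- 1
    for (j in which(colSums(Y) == 0)) Y[sample.int(nrow(Y), 1), j] <- 1
  }
  net <- association_network(sprintf("m%03d", seq_len(spec$n_microbes)),
                             sprintf("d%03d", seq_len(spec$n_diseases)), Y)
  list(net = net, microbe_block = mb, disease_block = db)
}

#' Generate a layered random disease DAG
#'
#' Terms are assigned to levels 0..depth-1 (level 0 = roots); every non-root
#' term receives 1..branching parents drawn from strictly shallower levels,
#' so the result is acyclic by construction.
#'
#' @param n_terms number of terms.
#' @param depth number of levels.
#' @param branching maximum parents per non-root term.
#' @param seed integer seed.
#' @return An \code{mda_ontology}.
#' @export
generate_random_dag <- function(n_terms, depth = 3L, branching = 2L,
                                seed = 1L) {
  stopifnot(n_terms >= 1L, depth >= 1L, branching >= 1L)
  set.seed(seed)
  terms <- sprintf("t%03d", seq_len(n_terms))
  depth <- min(depth, n_terms)
  level <- c(seq_len(depth) - 1L,                 # every level inhabited
             sample(seq_len(depth) - 1L, max(0L, n_terms - depth),
                    replace = TRUE))[seq_len(n_terms)]
  c2p <- list()
  for (i in which(level > 0L)) {
    shallower <- terms[level < level[i]]
    k <- sample.int(min(branching, length(shallower)), 1)
    c2p[[terms[i]]] <- sample(shallower, k)
  }
  disease_ontology(terms, c2p)
}

#' Build the full synthetic benchmark
#'
#' Bundles a planted-block network with a disease ontology in which
#' block-mate diseases share a block-level parent term under a common root,
#' so ontology-based semantic similarity correlates with the planted
#' structure. The planted assignments are returned for oracle scoring.
#'
#' @param spec an [synthetic_spec()].
#' @return List with \code{net}, \code{dag}, \code{truth} (block
#'   assignments), and \code{spec}.
#' @export
make_benchmark <- function(spec = synthetic_spec()) {
  g <- generate_block_bipartite(spec)
  blocks <- sprintf("block%02d", seq_len(spec$n_blocks))
  c2p <- stats::setNames(as.list(rep("root", spec$n_blocks)), blocks)
  for (j in seq_along(g$net$disease_ids))
    c2p[[g$net$disease_ids[j]]] <- blocks[g$disease_block[j]]
  dag <- disease_ontology(c("root", blocks, g$net$disease_ids), c2p)
  list(net = g$net, dag = dag,
       truth = list(microbe_block = g$microbe_block,
                    disease_block = g$disease_block),
       spec = spec)
}

#' Write a synthetic benchmark to a directory
#'
#' Writes \code{edgelist.tsv}, \code{ontology.tsv} and \code{truth.json}.
#'
#' @param bench result of [make_benchmark()].
#' @param dir output directory.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_edgelist(bench$net, file.path(dir, "edgelist.tsv"))
  edges <- unlist(lapply(names(bench$dag$child_to_parents), function(ch)
    paste(ch, bench$dag$child_to_parents[[ch]], sep = "\t")))
  writeLines(edges, file.path(dir, "ontology.tsv"))
  jsonlite::write_json(bench$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
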