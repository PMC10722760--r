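#' Negative sampling plan
#'
#' @param strategy one of \code{"random"}, \code{"kmeans"},
#'   \code{"gaussian_mixture"}, \code{"spectral_cocluster"},
#'   \code{"spectral_bicluster"}.
#' @param n_clusters number of clusters for the clustering strategies
#'   (default 23).
#' @param per_cluster either \code{"auto"} (ceil(n_total / n_clusters), then
#'   truncate to n_total) or a fixed integer drawn from every cluster with no
#'   truncation.
#' @param seed integer seed controlling clustering and draws.
#' @return A list of class \code{mda_sampling_plan}.
#' @export
negative_sampling_plan <- function(strategy = c("kmeans", "random",
                                                "gaussian_mixture",
                                                "spectral_cocluster",
                                                "spectral_bicluster"),
                                   n_clusters = 23L, per_cluster = "auto",
                                   seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(n_clusters >= 1L)
  if (!identical(per_cluster, "auto")) stopifnot(per_cluster >= 1L)
  structure(list(strategy = strategy, n_clusters = as.integer(n_clusters),
                 per_cluster = per_cluster, seed = as.integer(seed)),
            class = "mda_sampling_plan")
}

#' Enumerate candidate negative pairs
#'
#' All zero entries of \code{Y}, in row-major order (microbe-major).
#'
#' @param net an \code{mda_network}.
#' @return Integer matrix with columns \code{microbe}, \code{disease}.
#' @export
candidate_negatives <- function(net) {
  stopifnot(inherits(net, "mda_network"))
  idx <- which(t(net$Y) == 0) # transpose => row-major enumeration of Y
  nd <- ncol(net$Y)
  cbind(microbe = (idx - 1L) %/% nd + 1L, disease = (idx - 1L) %% nd + 1L)
}

# Dhillon-style spectral co-clustering row labels: normalize the candidate
# feature matrix, embed rows with the leading singular vectors (skipping the
# trivial first), k-means the embedding.
.spectral_rowlabels <- function(X, k, variant = c("cocluster", "bicluster"),
                                seed) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  X <- X - min(X) # non-negativity for the degree normalization
  r <- rowSums(X) + 1e-12
  c <- colSums(X) + 1e-12
  An <- X / sqrt(r)
  An <- sweep(An, 2, sqrt(c), "/")
  l <- ceiling(log2(max(k, 2)))
  nv <- min(l + 1L, ncol(An), nrow(An))
  sv <- svd(An, nu = nv, nv = 0)
  if (variant == "cocluster") {
    Z <- sv$u[, seq(2, nv), drop = FALSE] / sqrt(r)
  } else {
    # bicluster variant keeps the leading vectors including the first,
    # capturing checkerboard block structure in a simplified form
    Z <- sv$u[, seq_len(min(l + 1L, nv)), drop = FALSE]
  }
  set.seed(seed)
  stats::kmeans(Z, centers = k, nstart = 5, iter.max = 50)$cluster
}

#' @importFrom mclust Mclust mclustBIC
.cluster_candidates <- function(features, plan) {
  k <- plan$n_clusters
  set.seed(plan$seed)
  switch(plan$strategy,
    kmeans = stats::kmeans(features, centers = k, nstart = 5,
                           iter.max = 50)$cluster,
    gaussian_mixture = {
      # Mclust resolves mclustBIC in the caller's scope; the importFrom
      # above makes it visible through the package namespace
      fit <- Mclust(features, G = k, modelNames = "EII", verbose = FALSE)
      if (is.null(fit)) stop("Gaussian mixture clustering failed to fit")
      fit$classification
    },
    spectral_cocluster = .spectral_rowlabels(features, k, "cocluster",
                                             plan$seed),
    spectral_bicluster = .spectral_rowlabels(features, k, "bicluster",
                                             plan$seed),
    stop("unknown strategy")
  )
}

#' Select negative training pairs
#'
#' \code{strategy = "random"} draws \code{n_total} candidates uniformly
#' without replacement. The clustering strategies fit the named clustering on
#' the candidate feature rows and draw \code{per_cluster} pairs from each
#' non-empty cluster without replacement (clusters smaller than
#' \code{per_cluster} contribute all members); with \code{per_cluster =
#' "auto"} the draw is \code{ceiling(n_total / n_clusters)} per cluster,
#' truncated uniformly at random to exactly \code{n_total}. With an explicit
#' \code{per_cluster} the selection is not truncated (so 23 clusters x 196
#' per cluster yields 4508 when every cluster is large enough).
#'
#' @param features numeric matrix, one row per candidate pair (the clustering
#'   space; the pipeline uses the initial fused-similarity pair vectors).
#' @param candidates integer matrix from [candidate_negatives()].
#' @param plan an [negative_sampling_plan()].
#' @param n_total number of negatives wanted (ignored when \code{per_cluster}
#'   is an explicit integer).
#' @return Integer matrix (microbe, disease) of selected pairs.
#' @export
sample_negatives <- function(features, candidates, plan, n_total) {
  candidates <- as.matrix(candidates)
  n_cand <- nrow(candidates)
  auto <- identical(plan$per_cluster, "auto")
  if (auto && n_total > n_cand)
    stop("n_total exceeds the number of candidate negatives")
  if (plan$strategy == "random") {
    set.seed(plan$seed)
    sel <- sample.int(n_cand, n_total)
    return(candidates[sel, , drop = FALSE])
  }
  if (nrow(features) != n_cand)
    stop("feature rows must match candidate count")
  if (plan$n_clusters > n_cand)
    stop("more clusters than candidate negatives")
  labels <- .cluster_candidates(features, plan)
  per <- if (auto) ceiling(n_total / plan$n_clusters) else plan$per_cluster
  set.seed(plan$seed + 1L)
  sel <- unlist(lapply(split(seq_len(n_cand), labels), function(members) {
    if (length(members) <= per) members
    else sample(members, per)
  }), use.names = FALSE)
  if (auto && length(sel) > n_total) sel <- sample(sel, n_total)
  if (auto && length(sel) < n_total) {
    pool <- setdiff(seq_len(n_cand), sel)
    sel <- c(sel, sample(pool, n_total - length(sel)))
  }
  candidates[sel, , drop = FALSE]
}
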