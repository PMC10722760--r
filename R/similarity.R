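#' Similarity configuration
#'
#' @param FC semantic decay factor in (0, 1); each step away from a disease
#'   along the ontology multiplies the semantic contribution by \code{FC}.
#' @param alpha_d,alpha_m Gaussian interaction profile (GIP) bandwidth
#'   numerators for diseases and microbes.
#' @param sigmoid_norm_d,sigmoid_norm_m positive scalars dividing the inner
#'   product inside the sigmoid (tanh) kernel. Defaults (\code{NULL}) resolve
#'   at bundle-build time to the number of diseases and microbes respectively.
#' @return A list of class \code{mda_similarity_config}.
#' @export
similarity_config <- function(FC = 0.5, alpha_d = 1, alpha_m = 1,
                              sigmoid_norm_d = NULL, sigmoid_norm_m = NULL) {
  stopifnot(FC > 0, FC < 1, alpha_d > 0, alpha_m > 0)
  if (!is.null(sigmoid_norm_d)) stopifnot(sigmoid_norm_d > 0)
  if (!is.null(sigmoid_norm_m)) stopifnot(sigmoid_norm_m > 0)
  structure(list(FC = FC, alpha_d = alpha_d, alpha_m = alpha_m,
                 sigmoid_norm_d = sigmoid_norm_d,
                 sigmoid_norm_m = sigmoid_norm_m),
            class = "mda_similarity_config")
}

#' Semantic contributions of ancestors to a disease term
#'
#' Computes \code{SC_d(k)} for every term \code{k} in \code{T(d)} (the
#' ancestors of \code{d} plus \code{d} itself): \code{SC_d(d) = 1} and
#' \code{SC_d(k) = max over children k' of k inside T(d) of FC * SC_d(k')},
#' i.e. contributions decay by \code{FC} per step away from \code{d}.
#'
#' @param dag an \code{mda_ontology}.
#' @param d a term identifier present in the ontology.
#' @param FC decay factor in (0, 1).
#' @return Named numeric vector over \code{T(d)}.
#' @export
semantic_contributions <- function(dag, d, FC = 0.5) {
  stopifnot(inherits(dag, "mda_ontology"), FC > 0, FC < 1)
  if (!(d %in% dag$terms)) stop("unknown term: ", d)
  # breadth-first walk child -> parent; the max-over-children recursion
  # resolves to FC^(shortest upward distance), reached by relaxation
  sc <- stats::setNames(1, d)
  frontier <- d
  while (length(frontier) > 0L) {
    nxt <- character()
    for (k in frontier) {
      ps <- dag$child_to_parents[[k]]
      if (is.null(ps)) next
      for (p in ps) {
        cand <- FC * sc[[k]]
        if (is.na(sc[p]) || cand > sc[[p]]) {
          sc[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  sc
}

#' Final semantic value of a disease
#'
#' Sum of semantic contributions over all terms in \code{T(d)}.
#'
#' @param contributions named vector from [semantic_contributions()].
#' @return scalar.
#' @export
semantic_value <- function(contributions) {
  if (length(contributions) == 0L) stop("empty contribution map")
  sum(contributions)
}

#' DAG-based disease semantic similarity matrix
#'
#' \code{DS(i, j)} is the sum of both diseases' contributions over their
#' shared ancestor set, divided by the sum of their semantic values. Diseases
#' absent from the ontology get 0 off-diagonal and 1 on the diagonal.
#'
#' @param dag an \code{mda_ontology} (may be empty).
#' @param diseases ordered character vector of disease identifiers.
#' @param cfg an [similarity_config()].
#' @return Symmetric matrix with unit diagonal.
#' @export
disease_semantic_similarity <- function(dag, diseases, cfg = similarity_config()) {
  n <- length(diseases)
  DS <- diag(1, n)
  dimnames(DS) <- list(diseases, diseases)
  known <- diseases[diseases %in% dag$terms]
  if (length(known) < 2L) return(DS)
  sc <- lapply(known, function(d) semantic_contributions(dag, d, cfg$FC))
  names(sc) <- known
  semv <- vapply(sc, sum, numeric(1))
  for (a in seq_len(length(known) - 1L)) {
    for (b in seq(a + 1L, length(known))) {
      sa <- sc[[a]]; sb <- sc[[b]]
      shared <- intersect(names(sa), names(sb))
      if (length(shared) > 0L) {
        v <- sum(sa[shared] + sb[shared]) / (semv[[a]] + semv[[b]])
        i <- match(known[a], diseases); j <- match(known[b], diseases)
        DS[i, j] <- DS[j, i] <- v
      }
    }
  }
  DS
}

#' Gaussian interaction profile (GIP) kernel
#'
#' \code{K(i, j) = exp(-gamma * ||P_i - P_j||^2)} with the bandwidth
#' \code{gamma = alpha / mean(||P_i||^2)} set from the mean squared profile
#' norm over all rows.
#'
#' @param P profile matrix (one binary profile per row).
#' @param alpha bandwidth numerator.
#' @return List with \code{K} (kernel matrix) and \code{gamma}.
#' @export
gip_similarity <- function(P, alpha = 1) {
  P <- as.matrix(P)
  n <- nrow(P)
  ss <- rowSums(P^2)
  msq <- mean(ss)
  if (msq == 0)
    stop("degenerate GIP bandwidth: all profiles are zero (division by zero)")
  gamma <- alpha / msq
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0 # numerical noise
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  list(K = K, gamma = gamma)
}

#' Cosine similarity between profiles
#'
#' \code{K(i, j) = P_i . P_j / (||P_i|| ||P_j||)}; any pairing that involves
#' an all-zero profile is 0 (including that profile's diagonal entry).
#'
#' @param P profile matrix (one profile per row).
#' @return kernel matrix.
#' @export
cosine_profile_similarity <- function(P) {
  P <- as.matrix(P)
  nrm <- sqrt(rowSums(P^2))
  K <- tcrossprod(P)
  denom <- outer(nrm, nrm)
  K <- ifelse(denom > 0, K / denom, 0)
  K <- pmin(pmax(K, 0), 1) # clip float noise just past the bounds
  (K + t(K)) / 2
}

#' Sigmoid (tanh) kernel similarity between profiles
#'
#' \code{K(i, j) = tanh(P_i . P_j / norm)}.
#'
#' @param P profile matrix (one profile per row).
#' @param norm positive scalar divisor.
#' @return kernel matrix.
#' @export
sigmoid_kernel_similarity <- function(P, norm) {
  if (!is.numeric(norm) || norm <= 0) stop("sigmoid norm must be > 0")
  tanh(tcrossprod(as.matrix(P)) / norm)
}

#' Microbe functional similarity from disease semantic similarity
#'
#' For microbes with disease sets \code{D_i} (size p) and \code{D_j} (size q),
#' each disease is matched to its best counterpart in the other set via
#' \code{DS}, and the matched scores are summed and divided by \code{p + q}.
#' An isolated microbe (empty disease set) gets 0 off-diagonal; the diagonal
#' is 1.
#'
#' @param net an \code{mda_network}.
#' @param DS disease semantic similarity matrix (diseases in network order).
#' @return Symmetric matrix \code{FMS} with unit diagonal.
#' @export
microbe_functional_similarity <- function(net, DS) {
  stopifnot(inherits(net, "mda_network"))
  Y <- net$Y
  nd <- ncol(Y)
  if (!all(dim(DS) == c(nd, nd))) stop("DS dimension must match disease count")
  nm <- nrow(Y)
  p <- rowSums(Y)
  # best[d, j] = max over d' in D_j of DS[d, d']; 0 when D_j empty
  best <- matrix(0, nd, nm)
  for (j in seq_len(nm)) {
    Dj <- which(Y[j, ] == 1)
    if (length(Dj) > 0L)
      best[, j] <- apply(DS[, Dj, drop = FALSE], 1, max)
  }
  # S1[i, j] = sum over d in D_i of best[d, j]
  S1 <- Y %*% best
  FMS <- (S1 + t(S1)) / outer(p, p, "+")
  FMS[!is.finite(FMS)] <- 0
  FMS[p == 0, ] <- 0
  FMS[, p == 0] <- 0
  FMS <- (FMS + t(FMS)) / 2
  diag(FMS) <- 1
  dimnames(FMS) <- list(net$microbe_ids, net$microbe_ids)
  FMS
}

#' Element-wise mean of four equally-sized kernel matrices
#'
#' @param matrices list of exactly 4 matrices of identical shape.
#' @return fused matrix.
#' @export
fuse_kernels <- function(matrices) {
  if (!is.list(matrices) || length(matrices) != 4L)
    stop("fusion requires exactly 4 matrices")
  dims <- lapply(matrices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("fusion requires matrices of identical shape")
  Reduce(`+`, matrices) / 4
}

#' Compute all similarity kernels and the fused matrices
#'
#' Builds the four disease kernels (semantic DS, GIP GDS, cosine CDS, sigmoid
#' SDS), the four microbe kernels (functional FMS, GIP GMS, cosine CMS,
#' sigmoid SMS) and the fused averages \code{FuD}, \code{FuM}. If
#' \code{mask_pairs} is supplied, those entries of \code{Y} are zeroed before
#' any profile-based kernel or FMS is computed (leakage-safe evaluation).
#'
#' @param net an \code{mda_network}.
#' @param dag an \code{mda_ontology} or \code{NULL} (semantic similarity then
#'   falls back to the identity structure: unit diagonal, zero elsewhere).
#' @param cfg an [similarity_config()].
#' @param mask_pairs optional integer matrix with columns (microbe index,
#'   disease index) whose \code{Y} entries are zeroed first.
#' @return List of class \code{mda_similarity_bundle} with the eight kernels,
#'   \code{FuD}, \code{FuM} and realized GIP bandwidths \code{gamma_d},
#'   \code{gamma_m}.
#' @export
build_similarity_bundle <- function(net, dag = NULL, cfg = similarity_config(),
                                    mask_pairs = NULL) {
  stopifnot(inherits(net, "mda_network"))
  Y <- net$Y
  if (!is.null(mask_pairs) && NROW(mask_pairs) > 0L) {
    mask_pairs <- as.matrix(mask_pairs)
    Y[mask_pairs[, 1:2, drop = FALSE]] <- 0
    net <- association_network(net$microbe_ids, net$disease_ids, Y)
  }
  nd <- length(net$disease_ids); nm <- length(net$microbe_ids)
  snd <- if (is.null(cfg$sigmoid_norm_d)) nd else cfg$sigmoid_norm_d
  snm <- if (is.null(cfg$sigmoid_norm_m)) nm else cfg$sigmoid_norm_m

  Pd <- profiles(net, "disease") # nd x nm
  Pm <- profiles(net, "microbe") # nm x nd

  if (is.null(dag)) {
    DS <- diag(1, nd); dimnames(DS) <- list(net$disease_ids, net$disease_ids)
  } else {
    DS <- disease_semantic_similarity(dag, net$disease_ids, cfg)
  }
  gd <- gip_similarity(Pd, cfg$alpha_d)
  gm <- gip_similarity(Pm, cfg$alpha_m)
  bundle <- list(
    DS = DS,
    GDS = gd$K,
    CDS = cosine_profile_similarity(Pd),
    SDS = sigmoid_kernel_similarity(Pd, snd),
    FMS = microbe_functional_similarity(net, DS),
    GMS = gm$K,
    CMS = cosine_profile_similarity(Pm),
    SMS = sigmoid_kernel_similarity(Pm, snm),
    gamma_d = gd$gamma, gamma_m = gm$gamma,
    config = cfg
  )
  bundle$FuD <- fuse_kernels(bundle[c("DS", "GDS", "CDS", "SDS")])
  bundle$FuM <- fuse_kernels(bundle[c("FMS", "GMS", "CMS", "SMS")])
  class(bundle) <- "mda_similarity_bundle"
  bundle
}

#' @export
print.mda_similarity_bundle <- function(x, ...) {
  cat(sprintf(
    "mda_similarity_bundle: %d diseases, %d microbes (gamma_d %.4g, gamma_m %.4g)\n",
    nrow(x$FuD), nrow(x$FuM), x$gamma_d, x$gamma_m))
  invisible(x)
}

#' Export a similarity bundle as a directory of TSV matrices
#'
#' Writes the ten matrices as headered TSVs plus \code{manifest.json}
#' recording the configuration and realized GIP bandwidths.
#'
#' @param bundle an \code{mda_similarity_bundle}.
#' @param dir output directory (created if absent).
#' @export
write_similarity_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- c("DS", "GDS", "CDS", "SDS", "FMS", "GMS", "CMS", "SMS", "FuD", "FuM")
  for (nm in mats)
    write_matrix_tsv(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")))
  jsonlite::write_json(
    list(gamma_d = bundle$gamma_d, gamma_m = bundle$gamma_m,
         config = unclass(bundle$config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
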