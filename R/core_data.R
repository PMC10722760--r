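#' Construct a bipartite microbe-disease association network
#'
#' The network is stored as a binary adjacency matrix \code{Y} with one row
#' per microbe and one column per disease; \code{Y[i, j] = 1} means microbe
#' \code{i} has a reported association with disease \code{j}.
#'
#' @param microbe_ids character vector of unique microbe identifiers (rows).
#' @param disease_ids character vector of unique disease identifiers (columns).
#' @param Y binary matrix, \code{length(microbe_ids)} rows by
#'   \code{length(disease_ids)} columns.
#' @return An object of class \code{mda_network}.
#' @export
association_network <- function(microbe_ids, disease_ids, Y) {
  microbe_ids <- as.character(microbe_ids)
  disease_ids <- as.character(disease_ids)
  if (length(microbe_ids) < 1L || length(disease_ids) < 1L)
    stop("need at least one microbe and one disease")
  if (anyDuplicated(microbe_ids)) stop("duplicate microbe identifiers")
  if (anyDuplicated(disease_ids)) stop("duplicate disease identifiers")
  Y <- as.matrix(Y)
  if (nrow(Y) != length(microbe_ids) || ncol(Y) != length(disease_ids))
    stop("Y dimensions do not match identifier lists")
  if (!all(Y %in% c(0, 1))) stop("Y entries must be 0 or 1")
  storage.mode(Y) <- "double"
  dimnames(Y) <- list(microbe_ids, disease_ids)
  structure(
    list(microbe_ids = microbe_ids, disease_ids = disease_ids, Y = Y),
    class = "mda_network"
  )
}

#' @export
print.mda_network <- function(x, ...) {
  cat(sprintf(
    "mda_network: %d microbes x %d diseases, %d associations (density %.2f%%)\n",
    length(x$microbe_ids), length(x$disease_ids), sum(x$Y),
    100 * mean(x$Y)
  ))
  invisible(x)
}

#' Read a microbe-disease association edge list
#'
#' Reads a two-column TSV (microbe_id, disease_id). Lines starting with
#' \code{#} and blank lines are ignored; duplicate edges collapse to one.
#' Node order is first-appearance order in the file.
#'
#' @param path path to a TSV file.
#' @return An \code{mda_network}.
#' @export
read_association_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # optional node-universe headers written by write_association_edgelist():
  # they fix id order and keep isolated nodes through a round trip
  hdr <- function(tag) {
    ln <- grep(paste0("^#", tag, "\t"), lines, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    strsplit(sub(paste0("^#", tag, "\t"), "", ln[1L]), "\t", fixed = TRUE)[[1L]]
  }
  declared_m <- hdr("microbes")
  declared_d <- hdr("diseases")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no associations: file is empty after comment/blank removal")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad) > 0L)
    stop(sprintf("parse error at line %d: expected 2 tab-separated fields, found %d",
                 idx[bad[1L]], nf[bad[1L]]))
  m <- vapply(fields, `[[`, character(1), 1L)
  d <- vapply(fields, `[[`, character(1), 2L)
  dup <- duplicated(paste0(m, "\r", d))
  m <- m[!dup]; d <- d[!dup]
  microbe_ids <- declared_m %||% unique(m)
  disease_ids <- declared_d %||% unique(d)
  if (!all(m %in% microbe_ids) || !all(d %in% disease_ids))
    stop("edge references an identifier missing from the declared node header")
  Y <- matrix(0, length(microbe_ids), length(disease_ids))
  Y[cbind(match(m, microbe_ids), match(d, disease_ids))] <- 1
  association_network(microbe_ids, disease_ids, Y)
}

#' Write an association network as a TSV edge list
#'
#' Two leading comment lines (\code{#microbes}, \code{#diseases}) declare the
#' node universes and their order, so a write/read round trip reproduces
#' \code{Y} exactly, including isolated nodes. Plain two-column edge lists
#' without these headers remain fully readable.
#'
#' @param net an \code{mda_network}.
#' @param path output file path.
#' @export
write_association_edgelist <- function(net, path) {
  stopifnot(inherits(net, "mda_network"))
  ij <- which(net$Y == 1, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  writeLines(c(paste(c("#microbes", net$microbe_ids), collapse = "\t"),
               paste(c("#diseases", net$disease_ids), collapse = "\t"),
               paste(net$microbe_ids[ij[, 1]], net$disease_ids[ij[, 2]],
                     sep = "\t")),
             path)
  invisible(path)
}

#' Construct a disease-ontology DAG
#'
#' @param terms character vector of term identifiers.
#' @param child_to_parents named list mapping a child term to a character
#'   vector of its parent terms.
#' @return An object of class \code{mda_ontology}.
#' @export
disease_ontology <- function(terms = character(), child_to_parents = list()) {
  terms <- unique(as.character(terms))
  all_named <- unique(c(terms, names(child_to_parents),
                        unlist(child_to_parents, use.names = FALSE)))
  terms <- unique(c(terms, all_named))
  parents <- lapply(child_to_parents, function(p) unique(as.character(p)))
  cyc <- .find_cycle(terms, parents)
  if (!is.null(cyc))
    stop("not a DAG: cycle detected (", paste(cyc, collapse = " -> "), ")")
  structure(list(terms = terms, child_to_parents = parents),
            class = "mda_ontology")
}

# Returns one directed cycle (as a term path) or NULL. Iterative DFS with
# colouring; edges run child -> parent.
.find_cycle <- function(terms, parents) {
  state <- stats::setNames(rep(0L, length(terms)), terms) # 0 new, 1 open, 2 done
  for (start in terms) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, next_i = 1L))
    path <- start
    state[[start]] <- 1L
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      ps <- parents[[top$node]]
      if (is.null(ps) || top$next_i > length(ps)) {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      } else {
        stack[[length(stack)]]$next_i <- top$next_i + 1L
        nb <- ps[[top$next_i]]
        if (state[[nb]] == 1L) {
          i <- match(nb, path)
          return(c(path[i:length(path)], nb))
        }
        if (state[[nb]] == 0L) {
          state[[nb]] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nb, next_i = 1L)
          path <- c(path, nb)
        }
      }
    }
  }
  NULL
}

#' @export
print.mda_ontology <- function(x, ...) {
  cat(sprintf("mda_ontology: %d terms, %d child->parent edges\n",
              length(x$terms), length(unlist(x$child_to_parents))))
  invisible(x)
}

#' Read a disease-ontology edge list
#'
#' TSV of (child, parent) pairs; \code{#} comments and blank lines allowed.
#' An empty file yields an empty (valid) ontology. A cycle raises an error
#' naming one offending cycle.
#'
#' @param path path to a TSV file.
#' @return An \code{mda_ontology}.
#' @export
read_ontology_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(disease_ontology())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad) > 0L)
    stop(sprintf("parse error at line %d: expected 2 tab-separated fields, found %d",
                 idx[bad[1L]], nf[bad[1L]]))
  child <- vapply(fields, `[[`, character(1), 1L)
  parent <- vapply(fields, `[[`, character(1), 2L)
  c2p <- split(parent, child)
  disease_ontology(terms = unique(c(child, parent)), child_to_parents = c2p)
}

#' Extract binary association profiles
#'
#' A microbe profile is its row of \code{Y} (length = number of diseases);
#' a disease profile is its column of \code{Y} (length = number of microbes).
#'
#' @param net an \code{mda_network}.
#' @param axis \code{"microbe"} or \code{"disease"}.
#' @return Matrix with one profile per row, rownames = identifiers.
#' @export
profiles <- function(net, axis = c("microbe", "disease")) {
  stopifnot(inherits(net, "mda_network"))
  axis <- match.arg(axis)
  if (axis == "microbe") net$Y else t(net$Y)
}

#' Degree summary of an association network
#'
#' @param net an \code{mda_network}.
#' @return List with min/max/mean degree per node set (full precision and
#'   1-decimal rounding) and the total edge count.
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "mda_network"))
  dm <- rowSums(net$Y)
  dd <- colSums(net$Y)
  edges <- sum(net$Y)
  list(
    edges = edges,
    microbe = list(min = min(dm), max = max(dm), mean = mean(dm),
                   mean_1dp = round(mean(dm), 1)),
    disease = list(min = min(dd), max = max(dd), mean = mean(dd),
                   mean_1dp = round(mean(dd), 1))
  )
}

#' Write a named numeric matrix as headered TSV
#' @param m matrix with dimnames.
#' @param path output file path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a headered TSV matrix written by [write_matrix_tsv()]
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}
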