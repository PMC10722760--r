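`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble initial pair feature vectors
#'
#' The row for pair (microbe i, disease j) is the fused disease similarity
#' row \code{FuD[j, ]} concatenated with the fused microbe similarity row
#' \code{FuM[i, ]}; width = number of diseases + number of microbes (1311 for
#' a 1177 x 134 network).
#'
#' @param bundle an \code{mda_similarity_bundle}.
#' @param pairs integer matrix with columns (microbe index, disease index).
#' @return numeric matrix, one row per pair.
#' @export
assemble_initial_features <- function(bundle, pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L)
    return(matrix(0, 0L, ncol(bundle$FuD) + ncol(bundle$FuM)))
  mi <- pairs[, 1]; dj <- pairs[, 2]
  if (any(mi < 1 | mi > nrow(bundle$FuM)) || any(dj < 1 | dj > nrow(bundle$FuD)))
    stop("pair index out of range")
  cbind(bundle$FuD[dj, , drop = FALSE], bundle$FuM[mi, , drop = FALSE],
        deparse.level = 0)
}

#' Assemble final pair feature vectors
#'
#' The row for pair (i, j) is \code{LD[j, ] ++ LM[i, ] ++ high_rank row}.
#' Attributes \code{low_cols} and \code{high_cols} mark the two blocks so the
#' LRF / HRF ablation slices can be taken exactly.
#'
#' @param emb list with GCN embeddings \code{LM}, \code{LD}.
#' @param hr high-rank feature matrix, row-aligned to \code{pairs}.
#' @param pairs integer matrix (microbe index, disease index).
#' @return numeric matrix with block-column attributes.
#' @export
assemble_final_features <- function(emb, hr, pairs) {
  pairs <- as.matrix(pairs)
  hr <- as.matrix(hr)
  if (nrow(hr) != nrow(pairs)) stop("high-rank rows misaligned with pairs")
  mi <- pairs[, 1]; dj <- pairs[, 2]
  if (any(mi < 1 | mi > nrow(emb$LM)) || any(dj < 1 | dj > nrow(emb$LD)))
    stop("pair index out of range")
  low <- cbind(emb$LD[dj, , drop = FALSE], emb$LM[mi, , drop = FALSE],
               deparse.level = 0)
  out <- cbind(low, hr, deparse.level = 0)
  attr(out, "low_cols") <- seq_len(ncol(low))
  attr(out, "high_cols") <- ncol(low) + seq_len(ncol(hr))
  out
}

#' Slice an assembled final-feature matrix by ablation tag
#'
#' @param final matrix from [assemble_final_features()].
#' @param tag \code{"LHRF"} (everything), \code{"LRF"} (embedding block) or
#'   \code{"HRF"} (auto-encoder block).
#' @return feature matrix.
#' @export
ablation_block <- function(final, tag = c("LHRF", "LRF", "HRF")) {
  tag <- match.arg(tag)
  switch(tag,
         LHRF = final[, , drop = FALSE],
         LRF = final[, attr(final, "low_cols"), drop = FALSE],
         HRF = final[, attr(final, "high_cols"), drop = FALSE])
}

#' Stratified k-fold split
#'
#' @param labels binary label vector.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return List of k disjoint, covering test-index sets with per-fold class
#'   proportions within one sample of global.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  .stratified_folds(labels, k, seed)
}

#' Binary classification metrics
#'
#' AUC is the Mann-Whitney probability that a random positive outscores a
#' random negative (ties credited 1/2); AUPR uses step interpolation of the
#' precision-recall curve; Acc/Pre/Recall/F1 are evaluated at
#' \code{score >= threshold} (precision and F1 are 0 when undefined).
#'
#' @param labels binary labels (0/1).
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return Named list: Acc, Pre, Recall, F1, AUC, AUPR.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
  o <- order(-scores)
  ls <- labels[o]; ss <- scores[o]
  grp_end <- which(c(ss[-1] != ss[-length(ss)], TRUE))
  tp <- cumsum(ls)[grp_end]
  n_seen <- grp_end
  prec <- tp / n_seen
  rec <- tp / np
  aupr <- sum(diff(c(0, rec)) * prec)
  pred <- as.integer(scores >= threshold)
  acc <- mean(pred == labels)
  tp2 <- sum(pred == 1L & labels == 1L)
  pre <- if (sum(pred == 1L) > 0) tp2 / sum(pred == 1L) else 0
  recall <- tp2 / np
  f1 <- if (pre + recall > 0) 2 * pre * recall / (pre + recall) else 0
  list(Acc = acc, Pre = pre, Recall = recall, F1 = f1, AUC = auc, AUPR = aupr)
}

# shared stage runner: similarities -> GCN -> DAE features for a given Y
# masking; returns function pieces used by CV and ranking
.train_feature_stages <- function(net, dag, sim_cfg, gcn_cfg, dae_opts,
                                  mask_pairs = NULL, dae_train_rows = NULL,
                                  all_pairs) {
  bundle <- build_similarity_bundle(net, dag, sim_cfg, mask_pairs = mask_pairs)
  net_used <- net
  if (!is.null(mask_pairs) && NROW(mask_pairs) > 0L) {
    Y <- net$Y
    Y[as.matrix(mask_pairs)[, 1:2, drop = FALSE]] <- 0
    net_used <- association_network(net$microbe_ids, net$disease_ids, Y)
  }
  gfit <- train_gcn(net_used, bundle$FuM, bundle$FuD, gcn_cfg)
  init_all <- assemble_initial_features(bundle, all_pairs)
  dcfg <- do.call(dae_config, c(list(input_dim = ncol(init_all)), dae_opts))
  train_X <- if (is.null(dae_train_rows)) init_all
             else init_all[dae_train_rows, , drop = FALSE]
  dfit <- train_dae(train_X, dcfg)
  hr <- dae_encode(dfit, init_all)
  final <- assemble_final_features(gfit, hr, all_pairs)
  list(bundle = bundle, gcn = gfit, dae = dfit, final = final)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Builds a balanced sample set (all positives plus cluster-sampled
#' negatives), then evaluates the cascade forest on stratified k-fold splits
#' of the pairs. In \code{mode = "faithful"} the similarity, GCN and
#' auto-encoder stages are trained once on the full network; in \code{mode =
#' "masked"} (leakage-safe) each fold's test positives are zeroed in \code{Y}
#' before those stages are trained, and the auto-encoder sees only
#' training-fold rows.
#'
#' @param net an \code{mda_network}.
#' @param dag an \code{mda_ontology} or \code{NULL}.
#' @param folds number of CV folds (default 10).
#' @param mode \code{"faithful"} or \code{"masked"}.
#' @param ablations character vector from \code{"LHRF"}, \code{"LRF"},
#'   \code{"HRF"}: feature blocks to evaluate (features are trained once per
#'   fold and shared across ablations).
#' @param seed master seed.
#' @param shuffle_labels permute the pair labels (permutation-null control).
#' @param sim_cfg,gcn_cfg,cascade_cfg stage configurations.
#' @param dae_opts list of [dae_config()] arguments other than
#'   \code{input_dim}.
#' @param plan an [negative_sampling_plan()]; defaults to kmeans with 23
#'   clusters seeded by \code{seed}.
#' @param n_negatives number of negatives (default: number of positives).
#' @return Object of class \code{mda_evaluation_report}: \code{per_fold}
#'   data frame, \code{summary} (mean and sd per ablation and metric), and
#'   the configuration snapshot.
#' @export
run_cross_validation <- function(net, dag = NULL, folds = 10L,
                                 mode = c("faithful", "masked"),
                                 ablations = "LHRF", seed = 1L,
                                 shuffle_labels = FALSE,
                                 sim_cfg = similarity_config(),
                                 gcn_cfg = gcn_config(),
                                 cascade_cfg = cascade_config(),
                                 dae_opts = list(),
                                 plan = NULL, n_negatives = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(ablations %in% c("LHRF", "LRF", "HRF")))
  if (is.null(plan)) plan <- negative_sampling_plan("kmeans", seed = seed)
  bundle_full <- build_similarity_bundle(net, dag, sim_cfg)
  pos <- which(net$Y == 1, arr.ind = TRUE)
  colnames(pos) <- c("microbe", "disease")
  cand <- candidate_negatives(net)
  n_neg <- n_negatives %||% nrow(pos)
  feats_cand <- assemble_initial_features(bundle_full, cand)
  negs <- sample_negatives(feats_cand, cand, plan, n_total = n_neg)
  pairs <- rbind(pos, negs)
  labels <- c(rep(1L, nrow(pos)), rep(0L, nrow(negs)))
  if (shuffle_labels) {
    set.seed(seed + 77L)
    labels <- sample(labels)
  }
  fold_sets <- stratified_kfold(labels, folds, seed)

  if (mode == "faithful") {
    stages <- .train_feature_stages(net, dag, sim_cfg, gcn_cfg, dae_opts,
                                    all_pairs = pairs)
  }
  rows <- list()
  for (f in seq_along(fold_sets)) {
    te <- fold_sets[[f]]
    tr <- setdiff(seq_len(nrow(pairs)), te)
    if (mode == "masked") {
      mask <- pairs[te[labels[te] == 1L], , drop = FALSE]
      stages <- .train_feature_stages(net, dag, sim_cfg, gcn_cfg, dae_opts,
                                      mask_pairs = mask, dae_train_rows = tr,
                                      all_pairs = pairs)
    }
    for (tag in ablations) {
      X <- ablation_block(stages$final, tag)
      ccfg <- cascade_cfg
      ccfg$seed <- cascade_cfg$seed + 131L * f
      model <- fit_cascade(X[tr, , drop = FALSE], labels[tr], ccfg)
      scores <- predict_cascade(model, X[te, , drop = FALSE])[, "1"]
      m <- compute_metrics(labels[te], scores)
      rows[[length(rows) + 1L]] <-
        data.frame(fold = f, ablation = tag, Acc = m$Acc, Pre = m$Pre,
                   Recall = m$Recall, F1 = m$F1, AUC = m$AUC, AUPR = m$AUPR)
    }
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("Acc", "Pre", "Recall", "F1", "AUC", "AUPR")
  summ <- do.call(rbind, lapply(split(per_fold, per_fold$ablation), function(d) {
    data.frame(ablation = d$ablation[1],
               metric = metrics,
               mean = vapply(metrics, function(m) mean(d[[m]]), numeric(1)),
               sd = vapply(metrics, function(m) stats::sd(d[[m]]), numeric(1)),
               row.names = NULL)
  }))
  structure(list(per_fold = per_fold, summary = summ,
                 mode = mode, folds = folds, seed = seed,
                 shuffle_labels = shuffle_labels,
                 n_positives = nrow(pos), n_negatives = nrow(negs),
                 plan = plan),
            class = "mda_evaluation_report")
}

#' @export
print.mda_evaluation_report <- function(x, ...) {
  cat(sprintf("mda_evaluation_report: %d-fold CV, mode=%s, %d pos / %d neg%s\n",
              x$folds, x$mode, x$n_positives, x$n_negatives,
              if (x$shuffle_labels) " (label-shuffled control)" else ""))
  for (tag in unique(x$summary$ablation)) {
    s <- x$summary[x$summary$ablation == tag, ]
    cat(sprintf("  %s: %s\n", tag,
                paste(sprintf("%s %.4f+/-%.4f", s$metric, s$mean, s$sd),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Rank candidate microbes for a disease
#'
#' \code{mode = "known"}: train on all known associations and rank every
#' microbe not already linked to the disease. \code{mode = "novel"}: zero the
#' disease's entire column before every training stage (the disease is
#' treated as completely new) and rank all microbes. Ties are broken by
#' microbe input order.
#'
#' @param net an \code{mda_network}.
#' @param dag an \code{mda_ontology} or \code{NULL}.
#' @param disease_id disease identifier present in the network.
#' @param mode \code{"known"} or \code{"novel"}.
#' @param top_k optional truncation of the returned list.
#' @param seed master seed.
#' @param sim_cfg,gcn_cfg,cascade_cfg,dae_opts,plan,n_negatives as in
#'   [run_cross_validation()].
#' @return data.frame (rank, microbe_id, score), scores non-increasing.
#' @export
rank_candidates <- function(net, dag = NULL, disease_id,
                            mode = c("known", "novel"), top_k = NULL,
                            seed = 1L,
                            sim_cfg = similarity_config(),
                            gcn_cfg = gcn_config(),
                            cascade_cfg = cascade_config(),
                            dae_opts = list(),
                            plan = NULL, n_negatives = NULL) {
  mode <- match.arg(mode)
  j0 <- match(disease_id, net$disease_ids)
  if (is.na(j0)) stop("unknown disease: ", disease_id)
  if (is.null(plan)) plan <- negative_sampling_plan("kmeans", seed = seed)

  if (mode == "novel") {
    Y <- net$Y
    Y[, j0] <- 0
    net_tr <- association_network(net$microbe_ids, net$disease_ids, Y)
    score_microbes <- seq_along(net$microbe_ids)
  } else {
    net_tr <- net
    score_microbes <- which(net$Y[, j0] == 0)
  }
  bundle <- build_similarity_bundle(net_tr, dag, sim_cfg)
  pos <- which(net_tr$Y == 1, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("training network has no positives")
  cand <- candidate_negatives(net_tr)
  if (mode == "novel") cand <- cand[cand[, 2] != j0, , drop = FALSE]
  feats_cand <- assemble_initial_features(bundle, cand)
  negs <- sample_negatives(feats_cand, cand, plan,
                           n_total = n_negatives %||% nrow(pos))
  train_pairs <- rbind(pos, negs)
  labels <- c(rep(1L, nrow(pos)), rep(0L, nrow(negs)))
  query_pairs <- cbind(score_microbes, j0)
  all_pairs <- rbind(train_pairs, query_pairs)

  gfit <- train_gcn(net_tr, bundle$FuM, bundle$FuD, gcn_cfg)
  init_all <- assemble_initial_features(bundle, all_pairs)
  dcfg <- do.call(dae_config, c(list(input_dim = ncol(init_all)), dae_opts))
  # transductive: the auto-encoder is unsupervised, and the query pairs are
  # exactly the rows to score (their associations are already hidden), so
  # including them keeps their codes in-distribution
  dfit <- train_dae(init_all, dcfg)
  hr <- dae_encode(dfit, init_all)
  final <- assemble_final_features(gfit, hr, all_pairs)

  tr_idx <- seq_len(nrow(train_pairs))
  model <- fit_cascade(final[tr_idx, , drop = FALSE], labels, cascade_cfg)
  scores <- predict_cascade(model,
                            final[-tr_idx, , drop = FALSE])[, "1"]
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(rank = seq_along(ord),
                    microbe_id = net$microbe_ids[score_microbes][ord],
                    score = scores[ord])
  attr(out, "disease_id") <- disease_id
  attr(out, "mode") <- mode
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  out
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys \code{similarity}, \code{gcn}, \code{dae}, \code{cascade},
#' \code{sampling}, \code{synthetic} map 1:1 onto the corresponding
#' constructor arguments; unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return List of typed configuration objects (absent sections are NULL,
#'   except \code{dae} which is returned as an argument list).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("similarity", "gcn", "dae", "cascade", "sampling", "synthetic")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L)
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  build <- function(section, ctor) {
    if (is.null(raw[[section]])) return(NULL)
    args <- raw[[section]]
    ok <- names(formals(ctor))
    bad <- setdiff(names(args), ok)
    if (length(bad) > 0L)
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  list(similarity = build("similarity", similarity_config),
       gcn = build("gcn", gcn_config),
       dae = raw$dae, # argument list; input_dim is data-dependent
       cascade = build("cascade", cascade_config),
       sampling = build("sampling", negative_sampling_plan),
       synthetic = build("synthetic", synthetic_spec))
}
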