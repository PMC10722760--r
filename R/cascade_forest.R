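#' Cascade (deep) forest configuration
#'
#' Each cascade layer holds \code{forests_per_layer} forests (half standard
#' random forests, half completely-random forests built from single random
#' split candidates). A layer's input is the base feature matrix augmented
#' with the previous layer's class-probability outputs; during training the
#' augmenting probabilities are out-of-fold (cross-fitted) so no tree ever
#' scores a row it saw. Depth grows until internal CV accuracy stops
#' improving.
#'
#' @param forests_per_layer number of forests per layer (default 4: 2 random
#'   forests + 2 completely-random forests).
#' @param n_estimators trees per forest (default 17).
#' @param cv_folds folds for the out-of-fold augmentation (default 5).
#' @param max_layers cap on cascade depth (default 10).
#' @param early_stop_patience layers without accuracy improvement before
#'   stopping (default 1).
#' @param seed integer seed.
#' @return A list of class \code{mda_cascade_config}.
#' @export
cascade_config <- function(forests_per_layer = 4L, n_estimators = 17L,
                           cv_folds = 5L, max_layers = 10L,
                           early_stop_patience = 1L, seed = 1L) {
  stopifnot(forests_per_layer >= 1L, n_estimators >= 1L, cv_folds >= 2L,
            max_layers >= 1L, early_stop_patience >= 1L)
  structure(list(forests_per_layer = as.integer(forests_per_layer),
                 n_estimators = as.integer(n_estimators),
                 cv_folds = as.integer(cv_folds),
                 max_layers = as.integer(max_layers),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "mda_cascade_config")
}

# Stratified k-fold test-index sets: per-class round-robin after a seeded
# shuffle, so class proportions per fold are within one sample of global.
.stratified_folds <- function(y, k, seed) {
  if (k > length(y)) stop("more folds than samples")
  set.seed(seed)
  folds <- vector("list", k)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
  }
  lapply(folds, sort)
}

# completely-random forests: every split picks one random feature with one
# random cut; standard forests use default mtry with gini splits
.fit_forest <- function(X, y, cfg, kind, seed) {
  if (kind == "random") {
    ranger::ranger(x = X, y = y, num.trees = cfg$n_estimators,
                   probability = TRUE, seed = seed, num.threads = 1)
  } else {
    ranger::ranger(x = X, y = y, num.trees = cfg$n_estimators,
                   probability = TRUE, splitrule = "extratrees",
                   num.random.splits = 1, mtry = 1,
                   seed = seed, num.threads = 1)
  }
}

.forest_prob <- function(forest, X) {
  p <- stats::predict(forest, data = X, num.threads = 1)$predictions
  p[, c("0", "1"), drop = FALSE]
}

.as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Fit a cascade forest
#'
#' @param X numeric feature matrix.
#' @param y binary labels (0/1), length \code{nrow(X)}.
#' @param cfg an [cascade_config()].
#' @return Object of class \code{mda_cascade}: fitted layers (each a list of
#'   forests), per-layer internal CV accuracy, and the depth retained.
#' @export
fit_cascade <- function(X, y, cfg = cascade_config()) {
  X <- .as_feature_matrix(X)
  if (length(y) != nrow(X)) stop("row/label count mismatch")
  yf <- factor(as.integer(y), levels = c(0L, 1L), labels = c("0", "1"))
  if (length(unique(yf[!is.na(yf)])) < 2L)
    stop("labels must contain both classes")
  n <- nrow(X)
  kinds <- rep(c("random", "crf"), length.out = cfg$forests_per_layer)
  layers <- list()
  accs <- numeric()
  aug <- NULL
  best_acc <- -Inf
  best_depth <- 0L
  for (t in seq_len(cfg$max_layers)) {
    F_t <- if (is.null(aug)) X else cbind(X, .as_feature_matrix(aug))
    colnames(F_t) <- paste0("V", seq_len(ncol(F_t)))
    folds <- .stratified_folds(as.integer(yf) - 1L, cfg$cv_folds,
                               cfg$seed + 1000L * t)
    oof <- matrix(NA_real_, n, 2L * cfg$forests_per_layer)
    forests <- vector("list", cfg$forests_per_layer)
    for (f in seq_len(cfg$forests_per_layer)) {
      cols <- (2L * f - 1L):(2L * f)
      for (fi in seq_along(folds)) {
        te <- folds[[fi]]
        tr <- setdiff(seq_len(n), te)
        m <- .fit_forest(F_t[tr, , drop = FALSE], yf[tr], cfg, kinds[f],
                         seed = cfg$seed + 7919L * t + 97L * f + fi)
        oof[te, cols] <- .forest_prob(m, F_t[te, , drop = FALSE])
      }
      forests[[f]] <- .fit_forest(F_t, yf, cfg, kinds[f],
                                  seed = cfg$seed + 7919L * t + 97L * f)
    }
    pos_cols <- seq(2L, 2L * cfg$forests_per_layer, by = 2L)
    mean_pos <- rowMeans(oof[, pos_cols, drop = FALSE])
    acc <- mean((mean_pos >= 0.5) == (yf == "1"))
    layers[[t]] <- forests
    accs[t] <- acc
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best_depth <- t
    }
    if (t - best_depth >= cfg$early_stop_patience) break
    aug <- oof
  }
  structure(list(layers = layers[seq_len(best_depth)], cv_accuracy = accs,
                 n_layers = best_depth, base_width = ncol(X), cfg = cfg),
            class = "mda_cascade")
}

#' @export
print.mda_cascade <- function(x, ...) {
  cat(sprintf("mda_cascade: %d layer(s), %d forests/layer, CV accuracy %s\n",
              x$n_layers, x$cfg$forests_per_layer,
              paste(sprintf("%.3f", x$cv_accuracy), collapse = " ")))
  invisible(x)
}

#' Predict class probabilities from a cascade forest
#'
#' Intermediate layers re-augment features exactly as in training, but with
#' full-layer predictions; the final score is the mean of the last layer's
#' forests' class probabilities.
#'
#' @param model an \code{mda_cascade}.
#' @param X feature matrix with the training base width.
#' @return Matrix with columns \code{"0"}, \code{"1"}; rows sum to 1.
#' @export
predict_cascade <- function(model, X) {
  X <- .as_feature_matrix(X)
  if (ncol(X) != model$base_width)
    stop("feature width ", ncol(X), " does not match training width ",
         model$base_width)
  aug <- NULL
  for (t in seq_len(model$n_layers)) {
    F_t <- if (is.null(aug)) X else cbind(X, .as_feature_matrix(aug))
    colnames(F_t) <- paste0("V", seq_len(ncol(F_t)))
    probs <- lapply(model$layers[[t]], function(fr) .forest_prob(fr, F_t))
    aug <- do.call(cbind, probs)
  }
  k <- length(model$layers[[model$n_layers]])
  out <- Reduce(`+`, lapply(seq_len(k), function(f)
    aug[, (2L * f - 1L):(2L * f), drop = FALSE])) / k
  out <- out / rowSums(out)
  colnames(out) <- c("0", "1")
  out
}

#' @export
predict.mda_cascade <- function(object, newdata, ...) {
  predict_cascade(object, newdata)
}

.classifier_registry <- new.env(parent = emptyenv())

#' Register a baseline classifier adapter
#'
#' The adapter signature is \code{function(X, y, X_test, seed)} returning
#' positive-class scores for \code{X_test}.
#'
#' @param name registry key.
#' @param fn adapter function.
#' @export
register_classifier <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .classifier_registry)
  invisible(name)
}

#' Fit a named classifier and score test rows
#'
#' \code{"cascade"} is built in (delegates to [fit_cascade()] /
#' [predict_cascade()]); other names must have been registered via
#' [register_classifier()].
#'
#' @param name classifier name.
#' @param X,y training features and binary labels.
#' @param X_test rows to score.
#' @param seed integer seed.
#' @param cascade_cfg optional [cascade_config()] for the built-in.
#' @return numeric vector of positive-class scores.
#' @export
fit_predict_classifier <- function(name, X, y, X_test, seed = 1L,
                                   cascade_cfg = NULL) {
  if (name == "cascade") {
    cfg <- if (is.null(cascade_cfg)) cascade_config(seed = seed) else cascade_cfg
    model <- fit_cascade(X, y, cfg)
    return(predict_cascade(model, X_test)[, "1"])
  }
  if (!exists(name, envir = .classifier_registry))
    stop("unknown classifier '", name, "'; registered: ",
         paste(c("cascade", ls(.classifier_registry)), collapse = ", "))
  get(name, envir = .classifier_registry)(X, y, X_test, seed)
}
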