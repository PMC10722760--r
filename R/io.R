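# Export/import helpers for trained-stage artifacts.

#' Export GCN embeddings and training log
#'
#' Writes \code{LM.tsv} and \code{LD.tsv} (id column + one column per
#' embedding dimension) and \code{training_log.csv} (epoch, loss).
#'
#' @param fit an \code{mda_gcn_fit} from [train_gcn()].
#' @param dir output directory (created if absent).
#' @param microbe_ids,disease_ids row identifiers; defaults to rownames or
#'   sequential ids.
#' @export
write_gcn_embeddings <- function(fit, dir, microbe_ids = NULL,
                                 disease_ids = NULL) {
  stopifnot(inherits(fit, "mda_gcn_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mi <- microbe_ids %||% rownames(fit$LM) %||% sprintf("m%d", seq_len(nrow(fit$LM)))
  di <- disease_ids %||% rownames(fit$LD) %||% sprintf("d%d", seq_len(nrow(fit$LD)))
  lm <- fit$LM; rownames(lm) <- mi
  ld <- fit$LD; rownames(ld) <- di
  colnames(lm) <- colnames(ld) <- paste0("e", seq_len(ncol(lm)))
  write_matrix_tsv(lm, file.path(dir, "LM.tsv"))
  write_matrix_tsv(ld, file.path(dir, "LD.tsv"))
  utils::write.csv(data.frame(epoch = seq_along(fit$losses),
                              loss = fit$losses),
                   file.path(dir, "training_log.csv"), row.names = FALSE)
  invisible(dir)
}

#' Serialize trained auto-encoder parameters to a portable JSON file
#'
#' A single text file: a header with the layer dimensions, seed and config,
#' followed by the flattened weights (column-major) and biases.
#'
#' @param fit an \code{mda_dae_fit} (or bare parameter list with a config
#'   attribute).
#' @param path output file path.
#' @export
write_dae_params <- function(fit, path) {
  params <- if (inherits(fit, "mda_dae_fit")) fit$params else fit
  cfg <- attr(params, "cfg")
  payload <- list(
    format = "mdapred-dae-1",
    encoder_dims = cfg$encoder_dims,
    decoder_dims = cfg$decoder_dims,
    seed = cfg$seed,
    kl_weight = cfg$kl_weight,
    kl_epsilon = cfg$kl_epsilon,
    params = lapply(params, function(p) list(dim = dim(p) %||% length(p),
                                             values = as.numeric(p)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read auto-encoder parameters written by [write_dae_params()]
#'
#' @param path file path.
#' @return Parameter list usable with [dae_forward()] / [dae_encode()].
#' @export
read_dae_params <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "mdapred-dae-1"))
    stop("unrecognized serialization format")
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$values, p$dim[1], p$dim[2])
    else as.numeric(p$values)
  })
  cfg <- dae_config(payload$encoder_dims[1],
                    encoder_dims = payload$encoder_dims,
                    kl_weight = payload$kl_weight,
                    kl_epsilon = payload$kl_epsilon, seed = payload$seed)
  attr(params, "cfg") <- cfg
  params
}

#' Persist a fitted cascade forest to a directory
#'
#' One RDS file per forest plus a JSON manifest (layer layout, base width,
#' configuration). Forest objects are native ranger fits, so the RDS files
#' are only portable across compatible ranger versions.
#'
#' @param model an \code{mda_cascade}.
#' @param dir output directory.
#' @export
save_cascade <- function(model, dir) {
  stopifnot(inherits(model, "mda_cascade"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(model$layers))
    for (f in seq_along(model$layers[[t]]))
      saveRDS(model$layers[[t]][[f]],
              file.path(dir, sprintf("layer%02d_forest%02d.rds", t, f)))
  jsonlite::write_json(
    list(format = "mdapred-cascade-1", n_layers = model$n_layers,
         forests_per_layer = lengths(model$layers),
         base_width = model$base_width, cv_accuracy = model$cv_accuracy,
         cfg = unclass(model$cfg)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cascade forest saved by [save_cascade()]
#'
#' @param dir directory path.
#' @return An \code{mda_cascade}.
#' @export
load_cascade <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "mdapred-cascade-1"))
    stop("unrecognized serialization format")
  layers <- lapply(seq_len(man$n_layers), function(t)
    lapply(seq_len(man$forests_per_layer[t]), function(f)
      readRDS(file.path(dir, sprintf("layer%02d_forest%02d.rds", t, f)))))
  cfg <- do.call(cascade_config, man$cfg)
  structure(list(layers = layers, cv_accuracy = man$cv_accuracy,
                 n_layers = man$n_layers, base_width = man$base_width,
                 cfg = cfg),
            class = "mda_cascade")
}
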