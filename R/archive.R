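# Model archives: a directory of diffable columnar text files plus a config
# snapshot, rather than a binary blob.

#' Save a model to a directory archive
#'
#' Writes one CSV per connectivity map (target index, afferent slot, source
#' index/position/channel, weight), the non-zero recurrent weights as a
#' triplet file, the configuration snapshot as YAML, and the training log.
#'
#' @param model an [build_model()] model.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in 1:3) {
    cn <- model$conn[[l]]
    df <- data.frame(target = rep(seq_len(nrow(cn$idx)), ncol(cn$idx)),
                     slot = rep(seq_len(ncol(cn$idx)), each = nrow(cn$idx)),
                     source = as.integer(cn$idx),
                     weight = as.numeric(cn$w))
    utils::write.csv(df, file.path(dir, sprintf("connectivity_l%d.csv", l)),
                     row.names = FALSE)
  }
  nz <- which(model$rw$W != 0, arr.ind = TRUE)
  utils::write.csv(data.frame(i = nz[, 1], j = nz[, 2],
                              w = model$rw$W[nz]),
                   file.path(dir, "recurrent_weights.csv"), row.names = FALSE)
  save_config(model$config, file.path(dir, "config.yaml"))
  meta <- list(seed = model$seed, trained = model$trained,
               ca = list(sigma_d = model$rw$sigma_d,
                         ceiling = model$rw$ceiling, alpha = model$ca_alpha))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (!is.null(model$log)) {
    utils::write.csv(model$log, file.path(dir, "training_log.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a model from a directory archive
#'
#' Rebuilds the model deterministically from the archived configuration and
#' seed (connectivity sampling is reproducible), then overwrites all weights
#' with the archived values.
#'
#' @param dir an archive written by [save_model()].
#' @return an `svc_model`.
#' @export
load_model <- function(dir) {
  config <- load_config(file.path(dir, "config.yaml"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  model <- build_model(config, seed = meta$seed)
  for (l in 1:3) {
    df <- utils::read.csv(file.path(dir, sprintf("connectivity_l%d.csv", l)))
    df <- df[order(df$slot, df$target), ]
    model$conn[[l]]$w <- matrix(df$weight, nrow(model$conn[[l]]$w))
    stopifnot(all(matrix(df$source, nrow(model$conn[[l]]$idx)) ==
                    model$conn[[l]]$idx))
  }
  rwf <- file.path(dir, "recurrent_weights.csv")
  if (file.exists(rwf)) {
    tr <- utils::read.csv(rwf)
    if (nrow(tr)) model$rw$W[cbind(tr$i, tr$j)] <- tr$w
  }
  model$trained <- unlist(meta$trained) %||% character(0)
  lgf <- file.path(dir, "training_log.csv")
  if (file.exists(lgf)) model$log <- utils::read.csv(lgf)
  model
}
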