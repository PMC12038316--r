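# Run configuration: architecture defaults, YAML io with schema checking,
# and the canned demonstration configurations.

#' Default run configuration
#'
#' The architecture block reproduces the reference parameters: three 32x32
#' layers; Layer 1 with 54 connections, radius 1 and sparseness 0.1; Layers 2
#' and 3 with 40 connections, radius 1.7 and sparseness 0.12 and 0.08; trace
#' proportion `eta = 0.8` in Layers 2-3 (Layer 1 always learns with the
#' purely associative rule); Mexican-hat lateral inhibition with radii
#' 0.2/1.5.  The training block runs 7 epochs of 5 build-up plus 4 update
#' presentations per patch.
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    architecture = list(
      layer1 = list(n_rows = 32L, n_cols = 32L, n_connections = 54L,
                    radius = 1, sparseness = 0.1, alpha = 1, eta = 0,
                    lateral_inhibition = list(enabled = TRUE, center = 0.2,
                                              surround = 1.5)),
      layer2 = list(n_rows = 32L, n_cols = 32L, n_connections = 40L,
                    radius = 1.7, sparseness = 0.12, alpha = 1, eta = 0.8,
                    lateral_inhibition = list(enabled = TRUE, center = 0.2,
                                              surround = 1.5)),
      layer3 = list(n_rows = 32L, n_cols = 32L, n_connections = 40L,
                    radius = 1.7, sparseness = 0.08, alpha = 1, eta = 0.8,
                    lateral_inhibition = list(enabled = TRUE, center = 0.2,
                                              surround = 1.5)),
      freq_ratio = 2,
      ca = list(alpha = 0.1, sigma_d = 4, ceiling = 1)
    ),
    training = list(n_epochs = 7L, n_update = 4L, n_buildup = 5L),
    demo = list(lambda = 0.9, beta = 1.0, recall_sparseness = 0.02,
                n_steps = 200L),
    seed = 1L
  )
}

#' Configuration for the alphanumeric-patch demonstration
#'
#' The layer-map demonstration with the two glyph patches uses purely
#' associative learning (`eta = 0` everywhere); all other parameters are the
#' defaults.
#'
#' @return a configuration list.
#' @export
config_alphanumeric_demo <- function() {
  cfg <- default_config()
  cfg$architecture$layer2$eta <- 0
  cfg$architecture$layer3$eta <- 0
  cfg
}

#' Configuration for the natural-scene demonstration
#'
#' The natural-scene demonstration uses sparseness 0.3, 0.4 and 0.4 for
#' Layers 1-3, no lateral inhibition, and purely associative learning.
#'
#' @return a configuration list.
#' @export
config_natural_demo <- function() {
  cfg <- config_alphanumeric_demo()
  cfg$architecture$layer1$sparseness <- 0.3
  cfg$architecture$layer2$sparseness <- 0.4
  cfg$architecture$layer3$sparseness <- 0.4
  for (l in paste0("layer", 1:3)) {
    cfg$architecture[[l]]$lateral_inhibition$enabled <- FALSE
  }
  cfg
}

# recursively overlay user values onto defaults, collecting unknown keys
merge_config <- function(defaults, user, prefix = "") {
  bad <- character(0)
  for (k in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% names(defaults)) {
      bad <- c(bad, full)
    } else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) {
        bad <- c(bad, full)
      } else {
        sub <- merge_config(defaults[[k]], user[[k]], full)
        defaults[[k]] <- sub$config
        bad <- c(bad, sub$bad)
      }
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  list(config = defaults, bad = bad)
}

#' Load a run configuration from YAML
#'
#' Missing keys are filled from [default_config()]; unknown keys are
#' rejected, each named in the error.
#'
#' @param path YAML (or JSON-compatible YAML) file; an empty file yields the
#'   pure defaults.
#' @return a configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  res <- merge_config(default_config(), user)
  if (length(res$bad)) {
    stop("unknown configuration key(s): ", paste(res$bad, collapse = ", "),
         call. = FALSE)
  }
  res$config
}

#' Save a configuration to YAML
#'
#' @param config a configuration list.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
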