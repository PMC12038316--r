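# Model assembly, the feedforward pass, and the training protocol.
#
# Layers are trained sequentially (Layer 1 to convergence before Layer 2,
# before Layer 3) so that each layer always learns from a stationary input
# distribution.  A training epoch presents every (patch, gaze) pair of the
# scene in a seeded random permutation; each visit comprises a number of
# trace build-up presentations with no synaptic update followed by update
# presentations (associative rule in Layer 1, trace rule in Layers 2-3,
# plus the continuous-attractor rule on the Layer-3 rates).

#' Presentation schedule for training
#'
#' @param n_epochs training epochs (default 7).
#' @param n_update presentations per patch visit with synaptic updates
#'   (default 4).
#' @param n_buildup presentations per visit that only build up the
#'   short-term memory trace (default 5; inert when `eta = 0`).
#' @param seed seed for the per-epoch patch permutations.
#' @return a `training_schedule` object.
#' @export
training_schedule <- function(n_epochs = 7L, n_update = 4L, n_buildup = 5L,
                              seed = 1L) {
  stopifnot(n_epochs >= 1L, n_update >= 1L, n_buildup >= 0L)
  structure(list(n_epochs = as.integer(n_epochs),
                 n_update = as.integer(n_update),
                 n_buildup = as.integer(n_buildup),
                 seed = as.integer(seed)),
            class = "training_schedule")
}

#' Assemble an untrained model
#'
#' Builds the Gabor bank, the three afferent connectivity maps (V1 -> Layer 1
#' -> Layer 2 -> Layer 3) with randomly initialised unit-norm weights, and
#' zeroed recurrent scene weights.
#'
#' @param config a configuration list, see [default_config()].
#' @param seed master seed; connectivity and weights use named substreams.
#' @return an object of class `svc_model`.
#' @export
build_model <- function(config = default_config(), seed = config$seed %||% 1L) {
  cfgs <- lapply(config$architecture[c("layer1", "layer2", "layer3")],
                 do.call, what = layer_config)
  bank <- build_gabor_bank()
  conn1 <- build_connectivity_v1(cfgs[[1]], bank,
                                 seed = derive_seed(seed, "connectivity-l1"),
                                 freq_ratio = config$architecture$freq_ratio %||% 2)
  conn2 <- build_connectivity(cfgs[[2]], c(cfgs[[1]]$n_rows, cfgs[[1]]$n_cols),
                              seed = derive_seed(seed, "connectivity-l2"))
  conn3 <- build_connectivity(cfgs[[3]], c(cfgs[[2]]$n_rows, cfgs[[2]]$n_cols),
                              seed = derive_seed(seed, "connectivity-l3"))
  ca <- config$architecture$ca %||% list()
  rw <- recurrent_weights(c(cfgs[[3]]$n_rows, cfgs[[3]]$n_cols),
                          sigma_d = ca$sigma_d %||% 4,
                          ceiling = ca$ceiling %||% 1)
  structure(list(config = config, seed = seed, bank = bank,
                 layers = cfgs, conn = list(conn1, conn2, conn3),
                 rw = rw, ca_alpha = ca$alpha %||% 0.1,
                 trained = character(0), log = NULL),
            class = "svc_model")
}

#' @export
print.svc_model <- function(x, ...) {
  cat(sprintf(paste0("<svc_model: 3 x 32x32 layers over 256x256x%d V1; ",
                     "trained stages: %s>\n"),
              x$bank$n_channels,
              if (length(x$trained)) paste(x$trained, collapse = ", ")
              else "none"))
  invisible(x)
}

# V1 inputs gathered at Layer 1's afferent sample points (independent of all
# learned weights, so cacheable per image).
v1_afferent_inputs <- function(model, img, bbox = NULL) {
  conn1 <- model$conn[[1]]
  px <- as.matrix(unclass(img))
  if (is.null(bbox)) bbox <- c(1L, nrow(px), 1L, ncol(px))
  lin <- gabor_responses_at(px, model$bank$kernels, conn1$row, conn1$col,
                            conn1$kid, bbox[1], bbox[2], bbox[3], bbox[4])
  matrix(pmax(conn1$sgn * lin, 0), nrow(conn1$idx))
}

layer_forward <- function(model, l, x_in) {
  cfg <- model$layers[[l]]
  h <- activate(model$conn[[l]], x_in)
  li <- cfg$lateral_inhibition
  if (isTRUE(li$enabled)) h <- lateral_inhibit(h, li$center, li$surround)
  set_sparseness(h, cfg$sparseness)
}

#' Feedforward pass through the model
#'
#' Encodes the image, then propagates V1 -> Layer 1 -> Layer 2, gain-modulates
#' the Layer-2 rates by the gaze direction into the scene frame, and drives
#' Layer 3.  No weights change.
#'
#' @param model an [build_model()] model (trained or not).
#' @param img a 256x256 [gray_image()].
#' @param gaze a [gaze_direction()] or quadrant string.
#' @param up_to highest layer to evaluate (1-3; default 3).
#' @param x1 optional precomputed [v1_afferent_inputs()] matrix.
#' @return list with rate matrices `y1`, `y2`, `y3` (those evaluated), the
#'   gain-modulated Layer-3 input `l3_input`, and the per-layer
#'   [set_sparseness()] details in `detail`.
#' @export
present <- function(model, img, gaze = "UL", up_to = 3L, x1 = NULL) {
  stopifnot(inherits(model, "svc_model"))
  px <- as.matrix(unclass(img))
  if (!all(dim(px) == c(256L, 256L))) {
    stop("expected a 256x256 image, got ", nrow(px), "x", ncol(px),
         call. = FALSE)
  }
  if (is.character(gaze)) gaze <- gaze_direction(gaze)
  if (is.null(x1)) x1 <- v1_afferent_inputs(model, px)
  out <- list()
  s1 <- layer_forward(model, 1L, x1)
  out$y1 <- s1$y
  detail <- list(s1)
  if (up_to >= 2L) {
    s2 <- layer_forward(model, 2L, as.numeric(s1$y))
    out$y2 <- s2$y
    detail <- c(detail, list(s2))
  }
  if (up_to >= 3L) {
    out$l3_input <- remap_by_gaze(out$y2, gaze)
    s3 <- layer_forward(model, 3L, as.numeric(out$l3_input))
    out$y3 <- s3$y
    detail <- c(detail, list(s3))
  }
  out$gaze <- gaze
  out$detail <- detail
  out
}

#' Train the model on a scene
#'
#' Runs the full protocol: for each layer in turn (1, then 2, then 3), for
#' each epoch, the scene's (patch, gaze) pairs are visited in a seeded random
#' permutation; per visit the short-term trace is reset, `n_buildup`
#' presentations build the trace without updates, then `n_update`
#' presentations apply the layer's learning rule (associative in Layer 1,
#' trace rule in Layers 2-3 with the layer's `eta`).  During Layer-3 visits
#' the continuous-attractor weights are also updated from the Layer-3 rates.
#' Optional fixation jitter presents randomly shifted copies of each patch.
#'
#' @param model an [build_model()] model.
#' @param scene a [scene_spec()].
#' @param schedule a [training_schedule()].
#' @param jitter_px if positive, each presentation shifts the patch uniformly
#'   in `[-jitter_px, jitter_px]` in both axes (trace learning then confers
#'   tolerance to fixation scatter). Default 0 (static presentations).
#' @param verbose print per-epoch progress.
#' @return the trained model, with a `log` data frame of per-presentation
#'   layer statistics.
#' @export
train <- function(model, scene, schedule = training_schedule(),
                  jitter_px = 0L, verbose = FALSE) {
  stopifnot(inherits(model, "svc_model"), inherits(scene, "scene_spec"))
  if (!length(scene$patches)) stop("empty scene", call. = FALSE)
  quads <- names(scene$patches)
  n_pres <- schedule$n_buildup + schedule$n_update
  log <- list()
  # static-image afferent inputs, cached per patch
  x1_cache <- lapply(scene$patches, function(p) {
    v1_afferent_inputs(model, as.matrix(unclass(p)))
  })
  for (l in 1:3) {
    cfg <- model$layers[[l]]
    withr_seed(derive_seed(schedule$seed, paste0("schedule-l", l)), {
      # cache of frozen lower-layer outputs per patch (valid within a stage)
      lower_cache <- new.env(parent = emptyenv())
      for (epoch in seq_len(schedule$n_epochs)) {
        for (q in sample(quads)) {
          ybar <- 0
          for (pres in seq_len(n_pres)) {
            if (jitter_px > 0L) {
              px <- shift_image(as.matrix(unclass(scene$patches[[q]])),
                                sample(seq(-jitter_px, jitter_px), 2L,
                                       replace = TRUE))
              x1 <- v1_afferent_inputs(model, px)
              key <- NULL
            } else {
              x1 <- x1_cache[[q]]
              key <- q
            }
            ff <- forward_cached(model, l, q, x1, key, lower_cache)
            st <- layer_forward(model, l, ff$x_in)
            ybar <- trace_step(ybar, st$y, cfg$eta)
            if (pres > schedule$n_buildup) {
              upd <- if (l == 1L) as.numeric(st$y) else as.numeric(ybar)
              model$conn[[l]] <- hebb_update(model$conn[[l]], ff$x_in,
                                             upd, cfg$alpha)
              if (l == 3L) {
                model$rw <- ca_update(model$rw, st$y, model$ca_alpha)
              }
            }
            log[[length(log) + 1L]] <- data.frame(
              stage = l, epoch = epoch, patch = q, presentation = pres,
              update = pres > schedule$n_buildup,
              mean_rate = mean(st$y), sparseness = st$a)
          }
        }
      }
    })
    model$trained <- c(model$trained, paste0("layer", l))
    if (verbose) message("stage layer ", l, " trained")
  }
  model$log <- do.call(rbind, log)
  model
}

# forward pass up to (but not through) layer l, caching frozen lower layers
forward_cached <- function(model, l, quadrant, x1, key, cache) {
  if (l == 1L) return(list(x_in = x1))
  ck <- if (!is.null(key)) paste0(key, "-", l) else NULL
  if (!is.null(ck) && !is.null(cache[[ck]])) return(cache[[ck]])
  y1 <- layer_forward(model, 1L, x1)$y
  if (l == 2L) {
    res <- list(x_in = as.numeric(y1))
  } else {
    y2 <- layer_forward(model, 2L, as.numeric(y1))$y
    res <- list(x_in = as.numeric(remap_by_gaze(y2, quadrant)))
  }
  if (!is.null(ck)) cache[[ck]] <- res
  res
}

# integer translation with zero fill
shift_image <- function(px, shift) {
  out <- matrix(0, nrow(px), ncol(px))
  sr <- shift[1]; sc <- shift[2]
  r_src <- max(1, 1 - sr):min(nrow(px), nrow(px) - sr)
  c_src <- max(1, 1 - sc):min(ncol(px), ncol(px) - sc)
  out[r_src + sr, c_src + sc] <- px[r_src, c_src]
  out
}
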