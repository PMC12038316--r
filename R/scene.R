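# Layer-3 machinery: gaze-direction gain modulation that places a fixation
# patch into the whole-scene frame, and the continuous attractor formed by
# distance-weighted associative recurrent connections.
#
# The whole scene spans +-70 degrees and is tiled by four gaze quadrants;
# each 32x32 fixation-patch representation is halved in size (2x2 block
# average) so that four patches fit into the 32x32 scene layer.

.quadrant_offsets <- list(UL = c(0L, 0L), UR = c(0L, 16L),
                          LL = c(16L, 0L), LR = c(16L, 16L))

#' Gaze direction for a scene quadrant
#'
#' @param quadrant one of `"UL"`, `"UR"`, `"LL"`, `"LR"`.
#' @return a `gaze_direction` object carrying the quadrant, the placement
#'   offset into the 32x32 scene frame, and the nominal world angle of the
#'   quadrant centre (azimuth, elevation; the whole scene covers +-70
#'   degrees, so quadrant centres sit at +-35 degrees).
#' @export
gaze_direction <- function(quadrant) {
  if (!is.character(quadrant) || length(quadrant) != 1L ||
      !quadrant %in% names(.quadrant_offsets)) {
    stop("invalid gaze quadrant: must be one of UL, UR, LL, LR", call. = FALSE)
  }
  off <- .quadrant_offsets[[quadrant]]
  angle <- c(azimuth = if (off[2] == 0L) -35 else 35,
             elevation = if (off[1] == 0L) 35 else -35)
  structure(list(quadrant = quadrant, offset = off, angle = angle),
            class = "gaze_direction")
}

#' Gain-modulate a fixation patch into the scene frame
#'
#' Implements the effect of gaze-direction gain modulation: the 32x32
#' Layer-2 rate map is reduced in size by two times (2x2 block averaging, so
#' total drive is conserved up to the averaging factor) and placed at the
#' gaze quadrant's position in the 32x32 whole-scene frame; all other
#' entries are zero.
#'
#' @param layer2_rates non-negative 32x32 rate matrix.
#' @param gaze a [gaze_direction()] (or quadrant string).
#' @return 32x32 matrix: the Layer-3 feedforward input field.
#' @export
remap_by_gaze <- function(layer2_rates, gaze) {
  if (is.character(gaze)) gaze <- gaze_direction(gaze)
  stopifnot(inherits(gaze, "gaze_direction"))
  r <- as.matrix(layer2_rates)
  if (!all(dim(r) == c(32L, 32L))) {
    stop("layer2_rates must be 32x32", call. = FALSE)
  }
  if (min(r) < 0) stop("rates must be non-negative", call. = FALSE)
  # 2x2 block average down to 16x16
  small <- 0.25 * (r[seq(1, 31, 2), seq(1, 31, 2)] +
                   r[seq(2, 32, 2), seq(1, 31, 2)] +
                   r[seq(1, 31, 2), seq(2, 32, 2)] +
                   r[seq(2, 32, 2), seq(2, 32, 2)])
  out <- matrix(0, 32L, 32L)
  out[gaze$offset[1] + 1:16, gaze$offset[2] + 1:16] <- small
  out
}

#' Initialise recurrent (continuous-attractor) weights
#'
#' @param dims scene-layer dimensions (default 32x32, N = 1024 neurons).
#' @param sigma_d scale of the Gaussian distance kernel, neuron units.
#' @param ceiling per-synapse weight ceiling.
#' @return a `recurrent_weights` object: symmetric non-negative `N x N`
#'   matrix `W` with zero diagonal plus the kernel parameters.
#' @export
recurrent_weights <- function(dims = c(32L, 32L), sigma_d = 4, ceiling = 1) {
  if (sigma_d <= 0) stop("sigma_d must be positive", call. = FALSE)
  n <- prod(dims)
  structure(list(W = matrix(0, n, n), dims = as.integer(dims),
                 sigma_d = sigma_d, ceiling = ceiling),
            class = "recurrent_weights")
}

#' Associative update of the continuous-attractor weights
#'
#' For each co-active pair the weight grows with the product of the rates and
#' a strictly decreasing function of the neurons' distance apart in the scene
#' frame, `exp(-d^2 / (2 sigma_d^2))`: nearby features in a scene end up more
#' strongly linked than distant ones.  `W` stays symmetric with a zero
#' diagonal; entries are clipped at the configured ceiling.
#'
#' @param rw a [recurrent_weights()] object.
#' @param y_map scene-layer rate map for one presentation.
#' @param alpha learning rate.
#' @return the updated `recurrent_weights`.
#' @export
ca_update <- function(rw, y_map, alpha = 0.1) {
  stopifnot(inherits(rw, "recurrent_weights"))
  y <- as.numeric(y_map)
  act <- which(y > 0)
  if (length(act) < 2L) return(rw)
  pos <- arrayInd(act, rw$dims)
  d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
  dk <- exp(-d2 / (2 * rw$sigma_d^2))
  dw <- alpha * outer(y[act], y[act]) * dk
  diag(dw) <- 0
  block <- rw$W[act, act] + dw
  hit <- block > rw$ceiling
  if (any(hit)) {
    if (!isTRUE(rw$ceiling_hit)) {
      message("recurrent weight ceiling (", rw$ceiling, ") reached")
      rw$ceiling_hit <- TRUE
    }
    block[hit] <- rw$ceiling
  }
  rw$W[act, act] <- block
  rw
}

#' Recall from the continuous attractor
#'
#' Iterates the map `rates = set_sparseness(W rates + cue)`, with both the
#' recurrent drive and the rates rescaled to unit maximum each step (the 0-1
#' rate convention of the layer maps, which also keeps the iteration
#' numerically bounded), returning the final rate map.
#'
#' @param rw a [recurrent_weights()] object.
#' @param cue_rates cue rate map (vector or matrix of N entries).
#' @param n_iter number of relaxation steps (>= 1).
#' @param a_target recall sparseness.
#' @return list with `y` (final rate matrix), `a` (its sparseness), and
#'   `degenerate` (`TRUE` when both the cue and the weights are all zero).
#' @export
ca_recall <- function(rw, cue_rates, n_iter = 20L, a_target = 0.08) {
  stopifnot(inherits(rw, "recurrent_weights"), n_iter >= 1L)
  cue <- as.numeric(cue_rates)
  if (all(cue == 0) && all(rw$W == 0)) {
    warning("all-zero cue and weights: degenerate recall")
    return(list(y = matrix(0, rw$dims[1], rw$dims[2]), a = 0,
                degenerate = TRUE))
  }
  r <- cue
  for (it in seq_len(n_iter)) {
    wr <- as.numeric(rw$W %*% r)
    if (max(wr) > 0) wr <- wr / max(wr)   # recurrent drive on the 0-1 scale
    r <- as.numeric(set_sparseness(wr + cue, a_target)$y)
    if (max(r) > 0) r <- r / max(r)
  }
  list(y = matrix(r, rw$dims[1], rw$dims[2]), a = sparseness(r),
       degenerate = FALSE)
}

#' Adaptation parameters for the bump-movement demonstration
#'
#' Firing-rate adaptation is a demonstration device: it makes the activity
#' packet (bump) of a continuous attractor move through the space, which is
#' the classic signature that distance-dependent recurrent weights are in
#' place.  With `beta = 0` the dynamics reduce to non-adapting recall.
#'
#' @param lambda adaptation decay per step, in `[0, 1)`.
#' @param beta adaptation strength (>= 0).
#' @return an `adaptation_state` object.
#' @export
adaptation_state <- function(lambda = 0.9, beta = 1.0) {
  stopifnot(lambda >= 0, lambda < 1, beta >= 0)
  structure(list(lambda = lambda, beta = beta), class = "adaptation_state")
}

#' Rate-weighted centroid of a bump
#'
#' @param rate_map non-negative rate matrix with at least one positive entry.
#' @return `c(row, col)` rate-weighted mean position.
#' @export
bump_centroid <- function(rate_map) {
  r <- as.matrix(rate_map)
  s <- sum(r)
  if (s <= 0) stop("all-zero rate map has no centroid", call. = FALSE)
  c(row = sum(row(r) * r) / s, col = sum(col(r) * r) / s)
}

#' Bump dynamics under firing-rate adaptation
#'
#' Per step the adaptation variable integrates the rates,
#' `a(t) = lambda a(t-1) + (1 - lambda) r(t-1)`, and the rates are refreshed
#' as `set_sparseness(W r - beta a)`, with the recurrent drive `W r` and the
#' rates each rescaled to unit maximum so that `beta` measures adaptation
#' strength relative to the peak recurrent drive.
#' The rate-weighted bump centroid is recorded at every step.
#'
#' @param rw a [recurrent_weights()] object.
#' @param init_rates initial rate map (e.g. a relaxed [ca_recall()] state).
#' @param adaptation an [adaptation_state()].
#' @param T number of steps (>= 1).
#' @param a_target sparseness of the bump.
#' @return list with `rates` (list of `T` rate matrices) and `centroid`
#'   (`T x 2` matrix of row/col positions).
#' @export
bump_dynamics <- function(rw, init_rates, adaptation = adaptation_state(),
                          T = 200L, a_target = 0.02) {
  stopifnot(inherits(rw, "recurrent_weights"),
            inherits(adaptation, "adaptation_state"), T >= 1L)
  r <- as.numeric(init_rates)
  a <- numeric(length(r))
  rates <- vector("list", T)
  centroid <- matrix(NA_real_, T, 2L, dimnames = list(NULL, c("row", "col")))
  for (t in seq_len(T)) {
    a <- adaptation$lambda * a + (1 - adaptation$lambda) * r
    wr <- as.numeric(rw$W %*% r)
    if (max(wr) > 0) wr <- wr / max(wr)   # recurrent drive on the 0-1 scale
    h <- wr - adaptation$beta * a
    r <- as.numeric(set_sparseness(h, a_target)$y)
    if (max(r) > 0) r <- r / max(r)
    m <- matrix(r, rw$dims[1], rw$dims[2])
    rates[[t]] <- m
    centroid[t, ] <- if (sum(r) > 0) bump_centroid(m) else c(NA_real_, NA_real_)
  }
  list(rates = rates, centroid = centroid)
}
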