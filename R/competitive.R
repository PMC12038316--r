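# One competitive layer: dot-product activation, Mexican-hat lateral
# inhibition, sparseness-constrained threshold-linear output, and the
# associative (Hebbian) and short-term-memory trace learning rules.  The
# same machinery serves Layers 1-3.

#' Synaptically weighted activation
#'
#' The activation of each neuron is the inner product of its afferent weight
#' vector with the corresponding input rates.
#'
#' @param conn a connectivity map (see [sample_afferents()] and friends).
#' @param rates_in non-negative input rates: either a vector/array indexed by
#'   `conn$idx` (the source layer's rates or a flattened V1 stack), or a
#'   pre-gathered `n_neurons x n_connections` matrix of per-afferent inputs.
#' @return activation matrix of the layer's dimensions.
#' @export
activate <- function(conn, rates_in) {
  x <- if (is.matrix(rates_in) && all(dim(rates_in) == dim(conn$idx))) {
    rates_in
  } else {
    v <- as.numeric(rates_in)
    if (length(v) != prod(conn$source_dims)) {
      stop("input length ", length(v), " does not match source dimensions ",
           paste(conn$source_dims, collapse = "x"), call. = FALSE)
    }
    matrix(v[conn$idx], nrow(conn$idx))
  }
  if (min(x) < 0) stop("input rates must be non-negative", call. = FALSE)
  h <- rowSums(conn$w * x)
  matrix(h, conn$dims[1], conn$dims[2])
}

# difference-of-Gaussians kernel, exactly zero-sum; cached per radii
dog_kernel <- local({
  cache <- new.env(parent = emptyenv())
  function(center_radius, surround_radius) {
    key <- paste(center_radius, surround_radius)
    if (!is.null(cache[[key]])) return(cache[[key]])
    h <- ceiling(4 * surround_radius)
    d2 <- outer((-h:h)^2, (-h:h)^2, "+")
    gc_ <- exp(-d2 / (2 * center_radius^2)); gc_ <- gc_ / sum(gc_)
    gs <- exp(-d2 / (2 * surround_radius^2)); gs <- gs / sum(gs)
    k <- gc_ - gs
    k <- k - mean(k)                     # exact zero sum
    cache[[key]] <- k
    k
  }
})

#' Mexican-hat lateral inhibition
#'
#' Convolves the activation map with a zero-sum difference-of-Gaussians
#' filter (narrow excitatory centre, broad inhibitory surround), with
#' reflective border handling.  This implements the mutual inhibition that
#' drives nearby neurons to learn different stimuli.
#'
#' @param h_map activation matrix.
#' @param center_radius,surround_radius Gaussian radii in neuron units
#'   (defaults 0.2 and 1.5); the centre must be narrower than the surround.
#' @return filtered activation matrix (same size; may be negative).
#' @export
lateral_inhibit <- function(h_map, center_radius = 0.2, surround_radius = 1.5) {
  if (center_radius <= 0 || surround_radius <= 0 ||
      center_radius >= surround_radius) {
    stop("need 0 < center_radius < surround_radius", call. = FALSE)
  }
  k <- dog_kernel(center_radius, surround_radius)
  hw <- (nrow(k) - 1L) %/% 2L
  nr <- nrow(h_map); nc <- ncol(h_map)
  pr <- c(rev(seq_len(hw) + 1L), seq_len(nr), nr - seq_len(hw))
  pc <- c(rev(seq_len(hw) + 1L), seq_len(nc), nc - seq_len(hw))
  pad <- h_map[pr, pc]
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      if (k[a, b] == 0) next
      out <- out + k[a, b] * pad[(a):(a + nr - 1L), (b):(b + nc - 1L)]
    }
  }
  out
}

#' Population sparseness of a rate vector
#'
#' `a = (sum(y)/n)^2 / (sum(y^2)/n)`: for binary rates this is the fraction
#' of active neurons; it is 1 for uniform positive rates, and defined as 0
#' for an all-zero vector.
#'
#' @param y non-negative rates (vector or matrix).
#' @return sparseness in `[0, 1]`.
#' @export
sparseness <- function(y) {
  y <- as.numeric(y)
  s2 <- sum(y^2)
  if (s2 == 0) return(0)
  n <- length(y)
  (sum(y) / n)^2 / (s2 / n)
}

#' Threshold-linear output at a target sparseness
#'
#' Finds the threshold `theta` such that the rates `y = max(0, h - theta)`
#' have the requested population sparseness, by bisection over
#' `[max(0, min(h)), max(h)]` (sparseness of the thresholded rates is non-increasing
#' in `theta` at the resolution of distinct activation values; ties are
#' resolved towards the smallest qualifying threshold).  The threshold is
#' never allowed below zero: a neuron whose post-inhibition activation is not
#' positive stays silent, so competition only ever selects the most activated
#' neurons.  If the target cannot be attained within the search range -- e.g.
#' when the active support is too small, or the map is constant -- the
#' closest attainable rates are returned with `achieved = FALSE`.
#'
#' @param h_map (post-inhibition) activation matrix or vector.
#' @param a_target target sparseness in (0, 1].
#' @param tol tolerance on the achieved sparseness (default 1e-3).
#' @param max_iter bisection iterations (default 60).
#' @return list with `y` (non-negative rates, same shape as `h_map`),
#'   `theta`, `a` (achieved sparseness), `achieved`, and `constant` (flag
#'   for a constant input map, whose rates are all zero).
#' @export
set_sparseness <- function(h_map, a_target, tol = 1e-3, max_iter = 60L) {
  if (a_target <= 0 || a_target > 1) {
    stop("a_target must lie in (0, 1]", call. = FALSE)
  }
  h <- as.numeric(h_map)
  shape <- function(y) {
    if (is.matrix(h_map)) matrix(y, nrow(h_map), ncol(h_map)) else y
  }
  if (max(h) - min(h) < .Machine$double.eps * max(abs(max(h)), 1)) {
    # constant map: no threshold can separate anything
    return(list(y = shape(h * 0), theta = min(h), a = 0, achieved = FALSE,
                constant = TRUE))
  }
  lo <- max(0, min(h)); hi <- max(h)
  if (hi <= lo) {                        # no positive activations at all
    return(list(y = shape(h * 0), theta = lo, a = 0, achieved = FALSE,
                constant = FALSE))
  }
  a_of <- function(th) sparseness(pmax(0, h - th))
  # smallest theta with a(theta) <= a_target (monotone predicate)
  if (a_of(lo) <= a_target + tol) {
    theta <- lo
  } else {
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      if (a_of(mid) > a_target) lo <- mid else hi <- mid
    }
    theta <- hi
    # at plateaus (tied activations) no theta attains the target from above;
    # fall back to the bracket side whose sparseness is closest to the target
    if (abs(a_of(hi) - a_target) > tol &&
        abs(a_of(lo) - a_target) < abs(a_of(hi) - a_target)) {
      theta <- lo
    }
  }
  y <- pmax(0, h - theta)
  a <- sparseness(y)
  list(y = shape(y), theta = theta, a = a,
       achieved = abs(a - a_target) <= tol, constant = FALSE)
}

#' Associative (Hebbian) weight update
#'
#' Applies `delta w_j = alpha * y * x_j` to each neuron's afferent weights and
#' renormalises every weight vector to unit Euclidean norm, which keeps
#' competitive learning stable.
#'
#' @param conn connectivity map.
#' @param x per-afferent input matrix (`n_neurons x n_connections`) or a
#'   source rate vector/array to be gathered through `conn$idx`.
#' @param y output rates (matrix or vector of length `n_neurons`).
#' @param alpha learning rate.
#' @return the updated connectivity map.
#' @export
hebb_update <- function(conn, x, y, alpha) {
  stopifnot(alpha > 0)
  xv <- if (is.matrix(x) && all(dim(x) == dim(conn$idx))) {
    x
  } else {
    matrix(as.numeric(x)[conn$idx], nrow(conn$idx))
  }
  yv <- as.numeric(y)
  live <- yv != 0                        # silent neurons keep their weights
  if (any(live)) {
    w <- conn$w[live, , drop = FALSE] + alpha * yv[live] * xv[live, , drop = FALSE]
    nrm <- sqrt(rowSums(w^2))
    nz <- nrm > 0
    w[nz, ] <- w[nz, ] / nrm[nz]
    conn$w[live, ] <- w
  }
  conn
}

#' One step of the short-term memory trace
#'
#' `ybar_tau = (1 - eta) * y_tau + eta * ybar_{tau-1}`: with `eta = 0` the
#' trace is just the instantaneous rate (purely associative learning); larger
#' `eta` lets inputs close together in time become associated.
#'
#' @param ybar_prev previous trace.
#' @param y current rates.
#' @param eta trace update proportion in `[0, 1)`.
#' @return updated trace, same shape as `y`.
#' @export
trace_step <- function(ybar_prev, y, eta) {
  stopifnot(eta >= 0, eta < 1)
  (1 - eta) * y + eta * ybar_prev
}

#' Trace-rule weight update
#'
#' `delta w_j = alpha * ybar * x_j`, i.e. the Hebbian rule with the
#' short-term memory trace in place of the instantaneous rate; with
#' `eta = 0` it is exactly [hebb_update()].
#'
#' @inheritParams hebb_update
#' @param ybar trace values from [trace_step()].
#' @return the updated connectivity map.
#' @export
trace_update <- function(conn, x, ybar, alpha) {
  hebb_update(conn, x, ybar, alpha)
}
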