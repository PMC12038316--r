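# Receptive-field mapping, selectivity metrics, and figure-style exports.
#
# A neuron's receptive field is mapped by presenting small probe patches
# (32x32 by default) cut from a 256x256 image and placed at their true
# position on a zero background, moved across the image on a regular lattice
# (2-pixel steps by default, giving a 113x113 response grid).  The forward
# pass during probing is identical to the one used in training, with the
# threshold re-solved for every probe.

#' Map a neuron's receptive field by systematic probing
#'
#' @param model a trained [build_model()] model.
#' @param img the 256x256 [gray_image()] whose content is probed.
#' @param layer layer of the recorded neuron (1-3).
#' @param neuron 1-based linear (column-major) index of the neuron in its
#'   32x32 layer.
#' @param gaze gaze direction applied during probing (matters for Layer 3).
#' @param probe_size probe side in pixels (default 32).
#' @param step lattice step in pixels (default 2).
#' @return an object of class `receptive_field_map`: the response matrix
#'   (`(256 - probe_size)/step + 1` per side) with probe-centre coordinates,
#'   plus the angular calibration (one 256-px fixation patch spans 70
#'   degrees of visual angle).
#' @export
map_receptive_field <- function(model, img, layer = 3L, neuron, gaze = "UL",
                                probe_size = 32L, step = 2L) {
  stopifnot(inherits(model, "svc_model"))
  px <- as.matrix(unclass(img))
  if (!all(dim(px) == c(256L, 256L))) {
    stop("expected a 256x256 image", call. = FALSE)
  }
  if (probe_size > nrow(px)) stop("probe larger than image", call. = FALSE)
  n_neurons <- prod(model$conn[[layer]]$dims)
  if (neuron < 1L || neuron > n_neurons) {
    stop("neuron index out of range", call. = FALSE)
  }
  if (is.character(gaze)) gaze <- gaze_direction(gaze)
  starts <- seq(1L, nrow(px) - probe_size + 1L, by = step)
  m <- length(starts)
  resp <- matrix(0, m, m)
  for (a in seq_len(m)) {
    u <- starts[a]
    for (b in seq_len(m)) {
      v <- starts[b]
      bbox <- c(u, u + probe_size - 1L, v, v + probe_size - 1L)
      x1 <- v1_afferent_inputs(model, px, bbox = bbox)
      out <- present(model, px, gaze = gaze, up_to = layer, x1 = x1)
      resp[a, b] <- as.numeric(out[[paste0("y", layer)]])[neuron]
    }
  }
  structure(list(response = resp,
                 centers_row = starts + (probe_size - 1) / 2,
                 centers_col = starts + (probe_size - 1) / 2,
                 probe_size = probe_size, step = step,
                 layer = layer, neuron = neuron, gaze = gaze$quadrant,
                 deg_per_px = 70 / 256),
            class = "receptive_field_map")
}

#' @export
print.receptive_field_map <- function(x, ...) {
  cat(sprintf(paste0("<receptive_field_map: layer %d neuron %d, %dx%d lattice",
                     " (probe %d px, step %d px), peak %.4g>\n"),
              x$layer, x$neuron, nrow(x$response), ncol(x$response),
              x$probe_size, x$step, max(x$response)))
  invisible(x)
}

#' Receptive-field size at half maximum
#'
#' Area of the map above 50% of its peak response, reported as the diameter
#' of the circle of equal area, in scene pixels and in degrees of visual
#' angle (256 px = 70 degrees).
#'
#' @param rf a [map_receptive_field()] result.
#' @return list with `area_px2`, `diameter_px`, `diameter_deg`.
#' @export
rf_size <- function(rf) {
  stopifnot(inherits(rf, "receptive_field_map"))
  peak <- max(rf$response)
  if (peak <= 0) return(list(area_px2 = 0, diameter_px = 0, diameter_deg = 0))
  n_above <- sum(rf$response >= peak / 2)
  area <- n_above * rf$step^2            # each lattice cell covers step^2 px
  diam <- 2 * sqrt(area / pi)
  list(area_px2 = area, diameter_px = diam, diameter_deg = diam * rf$deg_per_px)
}

#' Response selectivity index
#'
#' `|rate_A - rate_B| / (rate_A + rate_B)`: 0 for equal responses, 1 when
#' only one stimulus drives the neuron.
#'
#' @param rate_A,rate_B non-negative responses, not both zero.
#' @return selectivity in `[0, 1]`.
#' @export
selectivity_index <- function(rate_A, rate_B) {
  if (rate_A < 0 || rate_B < 0) stop("rates must be non-negative", call. = FALSE)
  if (rate_A + rate_B == 0) {
    stop("selectivity undefined for two zero responses", call. = FALSE)
  }
  abs(rate_A - rate_B) / (rate_A + rate_B)
}

#' Export a rate map as CSV and PNG
#'
#' Writes the raw rates as a headerless CSV grid and, with the rates scaled
#' to the range 0-1 (the convention used in the layer-map figures), as a
#' grayscale PNG heat map.
#'
#' @param rates 2-D rate matrix.
#' @param path base path; `.csv` and `.png` are appended.
#' @return invisibly, the two file paths written.
#' @export
export_rate_map <- function(rates, path) {
  rates <- as.matrix(rates)
  if (length(dim(rates)) != 2L) stop("rates must be 2-D", call. = FALSE)
  csv <- paste0(path, ".csv")
  pngf <- paste0(path, ".png")
  ok <- tryCatch({
    utils::write.table(rates, csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    scaled <- if (max(rates) > 0) rates / max(rates) else rates * 0
    png::writePNG(scaled, pngf)
    TRUE
  }, error = function(e) {
    stop("failed to export rate map to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(c(csv = csv, png = pngf))
}

#' Read back an exported rate-map CSV
#'
#' @param path the `.csv` file written by [export_rate_map()].
#' @return numeric matrix.
#' @export
read_rate_map <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
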