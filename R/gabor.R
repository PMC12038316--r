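# V1-like Gabor front end.
#
# The input stage mimics V1 simple cells: a bank of even-symmetric Gabor
# kernels at four octave-spaced spatial frequencies and four orientations,
# with the signed linear response split into a positive and a negative
# half-rectified channel (32 channels in all).  Kernels are forced to exact
# zero mean so responses are invariant to mean luminance, and normalised to
# unit energy so channels are comparable across scales.

gabor_kernel <- function(wavelength, theta, sigma = 0.5 * wavelength) {
  h <- ceiling(3 * sigma)
  d <- -h:h
  x <- outer(d * 0, d, "+")              # column offsets
  y <- outer(d, d * 0, "+")              # row offsets
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  k <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / wavelength)
  k <- k - mean(k)                       # exact DC balance
  k / sqrt(sum(k^2))
}

#' Build the V1 Gabor filter bank
#'
#' @param n_freq number of octave-spaced spatial frequencies (default 4).
#' @param n_orient number of orientations, evenly spaced over 180 degrees
#'   (default 4: 0, 45, 90, 135 degrees).
#' @param base_wavelength wavelength in pixels of the highest-frequency
#'   kernels.
#' @param octave_spacing multiplicative wavelength step between bands.
#' @return an object of class `gabor_bank`: `n_freq * n_orient` base kernels
#'   (each paired with its negation to give `2 * n_freq * n_orient` sign-split
#'   channels), plus per-kernel parameters. Base kernel `k` serves channels
#'   `2k - 1` (positive) and `2k` (negative); bands are ordered from high to
#'   low spatial frequency.
#' @export
build_gabor_bank <- function(n_freq = 4L, n_orient = 4L, base_wavelength = 4,
                             octave_spacing = 2) {
  if (n_freq < 1L || n_orient < 1L) {
    stop("n_freq and n_orient must be at least 1", call. = FALSE)
  }
  wl <- base_wavelength * octave_spacing^(seq_len(n_freq) - 1)
  ang <- (seq_len(n_orient) - 1) * pi / n_orient
  params <- expand.grid(orient = seq_len(n_orient), freq = seq_len(n_freq))
  params <- params[, c("freq", "orient")]
  params$wavelength <- wl[params$freq]
  params$theta <- ang[params$orient]
  kernels <- Map(gabor_kernel, params$wavelength, params$theta)
  structure(list(kernels = kernels, params = params,
                 n_freq = n_freq, n_orient = n_orient,
                 n_channels = 2L * nrow(params)),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank: %d freq x %d orient x 2 signs = %d channels>\n",
              x$n_freq, x$n_orient, x$n_channels))
  invisible(x)
}

# channel index (1..32) -> base kernel and sign
channel_kernel <- function(channel) (channel + 1L) %/% 2L
channel_sign <- function(channel) 1 - 2 * (channel %% 2L == 0L)

#' Encode an image into the V1 channel stack
#'
#' Convolves the (implicitly mean-subtracted) image with every base kernel
#' using reflective border handling, then splits each signed response into
#' half-rectified positive and negative channels.
#'
#' @param img a [gray_image()] or numeric matrix, 256x256 unless
#'   `check_size = FALSE`.
#' @param bank a [build_gabor_bank()] bank.
#' @param check_size require the standard 256x256 input.
#' @return a `height x width x n_channels` array of non-negative responses
#'   (class `v1_stack`).
#' @export
encode <- function(img, bank = build_gabor_bank(), check_size = TRUE) {
  px <- as.matrix(unclass(img))
  if (check_size && !all(dim(px) == c(256L, 256L))) {
    stop("expected a 256x256 image, got ", nrow(px), "x", ncol(px),
         call. = FALSE)
  }
  nr <- nrow(px); nc <- ncol(px)
  halfmax <- max(vapply(bank$kernels, function(k) (nrow(k) - 1L) %/% 2L, 1L))
  pr <- c(rev(seq_len(halfmax) + 1L), seq_len(nr),
          nr - seq_len(halfmax))        # reflective pad indices
  pc <- c(rev(seq_len(halfmax) + 1L), seq_len(nc), nc - seq_len(halfmax))
  pad <- px[pr, pc]
  fpad <- stats::fft(pad)
  np <- dim(pad)
  out <- array(0, dim = c(nr, nc, bank$n_channels))
  for (k in seq_along(bank$kernels)) {
    ker <- bank$kernels[[k]]
    h <- (nrow(ker) - 1L) %/% 2L
    kk <- matrix(0, np[1], np[2])
    ri <- ((-h:h) %% np[1]) + 1L
    ci <- ((-h:h) %% np[2]) + 1L
    kk[ri, ci] <- ker                    # kernel centred at (1,1), wrapped
    lin <- Re(stats::fft(fpad * stats::fft(kk), inverse = TRUE)) / prod(np)
    lin <- lin[halfmax + seq_len(nr), halfmax + seq_len(nc)]
    out[, , 2L * k - 1L] <- pmax(lin, 0)
    out[, , 2L * k] <- pmax(-lin, 0)
  }
  structure(out, class = "v1_stack")
}

#' Sampled V1 responses at afferent positions
#'
#' Computes the same quantity as [encode()] but only at a set of
#' `(row, col, channel)` sample points, by direct convolution restricted to
#' the non-zero extent of the image.  This is the fast path used for layer-1
#' afferents and for receptive-field probes (a probe is a crop on a zero
#' background, so only the crop's bounding box contributes).
#'
#' @param img numeric matrix (any values; zero-mean handling is implicit in
#'   the DC-balanced kernels).
#' @param bank a [build_gabor_bank()] bank.
#' @param rows,cols integer sample positions (1-based).
#' @param channels channel indices in `1..n_channels`.
#' @param bbox optional `c(rmin, rmax, cmin, cmax)` restricting the source
#'   pixels (default: the whole image).
#' @return numeric vector of non-negative responses, one per sample point.
#' @export
encode_at <- function(img, bank, rows, cols, channels, bbox = NULL) {
  px <- as.matrix(unclass(img))
  if (is.null(bbox)) bbox <- c(1L, nrow(px), 1L, ncol(px))
  kid <- channel_kernel(channels)
  sgn <- channel_sign(channels)
  lin <- gabor_responses_at(px, bank$kernels, as.integer(rows),
                            as.integer(cols), as.integer(kid),
                            as.integer(bbox[1]), as.integer(bbox[2]),
                            as.integer(bbox[3]), as.integer(bbox[4]))
  pmax(sgn * lin, 0)
}
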