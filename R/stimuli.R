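# Fixation-patch stimulus generation and image io.
#
# Training stimuli are 256x256 grayscale "visual fixation scene patches":
# either 3x3 grids of alphanumeric glyphs (so the topology of the
# representation can be followed from layer to layer), or seeded 1/f-noise
# natural-like images.  All values live in [0, 1].

# Embedded 5x7 bitmap font ('#' = stroke).  A fixed bitmap font avoids
# system-font nondeterminism; distinctness of the bitmaps is asserted in the
# test suite.
.svc_font <- c(
  "0" = ".###.#...##..###.#.###..##...#.###.",
  "1" = "..#...##....#....#....#....#...###.",
  "2" = ".###.#...#....#...#...#...#...#####",
  "3" = ".###.#...#....#..##.....##...#.###.",
  "4" = "...#...##..#.#.#..#.#####...#....#.",
  "5" = "######....####.....#....##...#.###.",
  "6" = "..##..#...#....####.#...##...#.###.",
  "7" = "#####....#...#...#...#....#....#...",
  "8" = ".###.#...##...#.###.#...##...#.###.",
  "9" = ".###.#...##...#.####....#...#..##..",
  "A" = ".###.#...##...#######...##...##...#",
  "B" = "####.#...##...#####.#...##...#####.",
  "C" = ".###.#...##....#....#....#...#.###.",
  "D" = "####.#...##...##...##...##...#####.",
  "E" = "######....#....####.#....#....#####",
  "F" = "######....#....####.#....#....#....",
  "G" = ".###.#...##....#.####...##...#.####",
  "H" = "#...##...##...#######...##...##...#",
  "I" = ".###...#....#....#....#....#...###.",
  "J" = "..####...#....#....#....##..#..##..",
  "K" = "#...##..#.#.#..##...#.#..#..#.#...#",
  "L" = "#....#....#....#....#....#....#####",
  "M" = "#...###.###.#.##.#.##...##...##...#",
  "N" = "#...###..##.#.##..###...##...##...#",
  "O" = ".###.#...##...##...##...##...#.###.",
  "P" = "####.#...##...#####.#....#....#....",
  "Q" = ".###.#...##...##...##.#.##..#..##.#",
  "R" = "####.#...##...#####.#.#..#..#.#...#",
  "S" = ".#####....#.....###.....#....#####.",
  "T" = "#####..#....#....#....#....#....#..",
  "U" = "#...##...##...##...##...##...#.###.",
  "V" = "#...##...##...##...##...#.#.#...#..",
  "W" = "#...##...##...##.#.##.#.###.###...#",
  "X" = "#...##...#.#.#...#...#.#.#...##...#",
  "Y" = "#...##...#.#.#...#....#....#....#..",
  "Z" = "#####....#...#...#...#...#....#####",
  " " = "..................................."
)

glyph_bitmap <- function(id) {
  s <- .svc_font[id]
  if (is.na(s)) stop("unknown glyph id: '", id, "'", call. = FALSE)
  matrix(strsplit(s, "")[[1]] == "#", nrow = 7, ncol = 5, byrow = TRUE) * 1
}

#' Grayscale image container
#'
#' A 2-D luminance field with values in `[0, 1]` plus a label.
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param label short descriptive string.
#' @return an object of class `gray_image` (a matrix with attributes).
#' @export
gray_image <- function(pixels, label = "") {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("gray_image pixel values must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, label = label, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image '%s' %dx%d, range [%.3f, %.3f]>\n",
              attr(x, "label"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Specify a 3x3 grid of glyphs
#'
#' The lower-right glyph is displaced by `offset_lr` pixels so the network's
#' topology can be traced through the layers.
#'
#' @param glyphs character vector of 9 glyph ids (digits, `A`-`Z`, or `" "`),
#'   filled row by row.
#' @param offset_lr integer `(dy, dx)` displacement of the lower-right glyph;
#'   must stay small relative to the cell size (at most cell/4).
#' @return an object of class `glyph_grid`.
#' @export
glyph_grid <- function(glyphs, offset_lr = c(3, 3)) {
  glyphs <- as.character(glyphs)
  if (length(glyphs) != 9L) stop("a glyph grid has exactly 9 slots", call. = FALSE)
  unknown <- setdiff(glyphs, names(.svc_font))
  if (length(unknown)) {
    stop("unknown glyph id: '", unknown[1], "'", call. = FALSE)
  }
  stopifnot(length(offset_lr) == 2L)
  structure(list(glyphs = matrix(glyphs, 3, 3, byrow = TRUE),
                 offset_lr = as.integer(round(offset_lr))),
            class = "glyph_grid")
}

#' Render a 3x3 alphanumeric fixation patch
#'
#' Glyphs are rasterised from the embedded 5x7 bitmap font by nearest-neighbour
#' upscaling onto a uniform 3x3 lattice spanning the central 75% of the field.
#' Background is 0, strokes are 1 (white-on-black; invert with `invert`).
#'
#' @param grid a [glyph_grid()].
#' @param size image side in pixels (default 256).
#' @param invert render black-on-white instead.
#' @return a [gray_image()] of dimension `size x size`.
#' @export
render_glyph_patch <- function(grid, size = 256L, invert = FALSE) {
  stopifnot(inherits(grid, "glyph_grid"))
  size <- as.integer(size)
  if (size < 32L) stop("size must be at least 32", call. = FALSE)
  img <- matrix(0, size, size)
  span <- round(0.75 * size)            # central lattice extent
  cell <- span %/% 3L
  orig <- (size - span) %/% 2L          # top-left of the lattice (0-based)
  scale <- max(1L, (cell * 7L) %/% 10L %/% 7L)  # glyph height ~70% of cell
  gh <- 7L * scale
  gw <- 5L * scale
  maxoff <- cell %/% 4L
  if (any(abs(grid$offset_lr) > maxoff)) {
    stop("offset_lr magnitude must be <= cell/4 (", maxoff, " px)", call. = FALSE)
  }
  for (i in 1:3) {
    for (j in 1:3) {
      bm <- glyph_bitmap(grid$glyphs[i, j])
      big <- bm[rep(1:7, each = scale), rep(1:5, each = scale)]
      r0 <- orig + (i - 1L) * cell + (cell - gh) %/% 2L
      c0 <- orig + (j - 1L) * cell + (cell - gw) %/% 2L
      if (i == 3L && j == 3L) {
        r0 <- r0 + grid$offset_lr[1]
        c0 <- c0 + grid$offset_lr[2]
      }
      rows <- (r0 + 1L):(r0 + gh)
      cols <- (c0 + 1L):(c0 + gw)
      keep_r <- rows >= 1L & rows <= size
      keep_c <- cols >= 1L & cols <= size
      img[rows[keep_r], cols[keep_c]] <-
        pmax(img[rows[keep_r], cols[keep_c]], big[keep_r, keep_c])
    }
  }
  if (invert) img <- 1 - img
  gray_image(img, label = paste0("glyphs:", paste(t(grid$glyphs), collapse = "")))
}

#' Seeded natural-like 1/f-noise image
#'
#' Generates an image whose amplitude spectrum falls as `1/f^spectrum_exponent`
#' (exponent 1 approximates the spectral statistics of natural scenes;
#' exponent 0 is white noise), rescaled to `[0, 1]`.
#'
#' @param seed integer seed; the same seed always yields the same image.
#' @param size image side in pixels (>= 64).
#' @param spectrum_exponent exponent of the radial amplitude fall-off.
#' @return a [gray_image()].
#' @export
make_natural_like <- function(seed, size = 256L, spectrum_exponent = 1) {
  size <- as.integer(size)
  if (size <= 0L) stop("size must be positive", call. = FALSE)
  if (size < 64L) stop("size must be at least 64", call. = FALSE)
  noise <- withr_seed(derive_seed(seed, "natural-like"), {
    matrix(stats::rnorm(size * size), size, size)
  })
  fr <- stats::fft(noise)
  k <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  rad <- sqrt(outer(k^2, k^2, "+"))
  amp <- ifelse(rad > 0, rad^(-spectrum_exponent), 0)
  img <- Re(stats::fft(fr * amp, inverse = TRUE)) / (size * size)
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng) else img <- img * 0
  gray_image(img, label = sprintf("natural-like seed=%d exp=%g",
                                  seed, spectrum_exponent))
}

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Read a grayscale image from PNG or PGM
#'
#' Colour PNG input is converted to luminance (Rec. 601 weights). PGM formats
#' P2 (ASCII) and P5 (binary) are supported.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @return a [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) {
      nchan <- dim(px)[3]
      px <- if (nchan >= 3L) {
        0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
      } else {
        px[, , 1]
      }
    }
    gray_image(pmin(pmax(px, 0), 1), label = basename(path))
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    stop("unsupported image format: '", ext, "' (use png or pgm)", call. = FALSE)
  }
}

#' Write a grayscale image to PNG or PGM
#'
#' Pixels are quantised to 8 bits; a write/read round trip preserves values to
#' within 1/255.
#'
#' @param img a [gray_image()] (any numeric matrix in `[0,1]` is accepted).
#' @param path destination ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- unclass(as.matrix(img))
  attributes(px) <- attributes(px)["dim"]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, path)
  } else if (ext == "pgm") {
    write_pgm(px, path)
  } else {
    stop("unsupported image format: '", ext, "' (use png or pgm)", call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  tok <- function() { # next whitespace-delimited token, skipping comments
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (!length(ch) || ch == "") stop("truncated PGM header", call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (!length(ch) || grepl("[[:space:]]", ch) || ch == "") break
      out <- paste0(out, ch)
    }
    out
  }
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", w * h))
  } else if (magic == "P2") {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[1:(w * h)]
  } else {
    stop("unsupported image format: PGM magic '", magic, "'", call. = FALSE)
  }
  gray_image(matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE),
             label = basename(path))
}

write_pgm <- function(px, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- as.integer(round(t(px) * 255))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px)), con, eos = NULL)
  writeBin(as.raw(v), con)
}

#' Bundle fixation patches with their gaze quadrants into a scene
#'
#' A whole scene is an assignment of fixation-patch images to gaze quadrants
#' `UL`, `UR`, `LL`, `LR` (upper/lower x left/right of the +-70 degree scene
#' frame).
#'
#' @param patches named list mapping quadrant labels to [gray_image()]s.
#' @param name scene name.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(patches, name = "scene") {
  if (!length(patches)) stop("a scene needs at least one patch", call. = FALSE)
  labs <- names(patches)
  if (is.null(labs) || anyDuplicated(labs) ||
      !all(labs %in% c("UL", "UR", "LL", "LR"))) {
    stop("patches must be uniquely named with quadrants UL/UR/LL/LR",
         call. = FALSE)
  }
  lapply(patches, function(p) stopifnot(inherits(p, "gray_image")))
  structure(list(patches = patches, name = name), class = "scene_spec")
}

#' The two alphanumeric demonstration patches
#'
#' Patch 1 carries the digits 1-9, patch 2 the letters A-I, each with the
#' lower-right glyph offset by `(3, 3)` pixels; they are placed in the upper
#' left and upper right quadrants of the scene frame (the lower quadrants stay
#' empty).
#'
#' @return a [scene_spec()] with patches `UL` (digits) and `UR` (letters).
#' @export
demo_scene_alphanumeric <- function() {
  p1 <- render_glyph_patch(glyph_grid(as.character(1:9)))
  p2 <- render_glyph_patch(glyph_grid(LETTERS[1:9]))
  scene_spec(list(UL = p1, UR = p2), name = "alphanumeric")
}

#' A natural-like two-patch demonstration scene
#'
#' Two seeded 1/f patches standing in for the left and right upper fixations
#' of a natural whole scene.
#'
#' @param seed master seed for the patch generator.
#' @return a [scene_spec()] with patches `UL` and `UR`.
#' @export
demo_scene_natural <- function(seed = 42L) {
  scene_spec(list(UL = make_natural_like(seed),
                  UR = make_natural_like(seed + 1L)),
             name = "natural-like")
}
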