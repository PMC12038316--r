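test_that("glyph rendering is deterministic and respects the grid geometry", {
  g <- glyph_grid(as.character(1:9), offset_lr = c(3, 3))
  img1 <- render_glyph_patch(g)
  img2 <- render_glyph_patch(g)
  expect_identical(unclass(img1), unclass(img2))
  expect_equal(dim(img1), c(256L, 256L))
  expect_true(all(img1 %in% c(0, 1)))

  # the lower-right glyph is displaced: rendering with and without the offset
  # differs only inside the lower-right cell
  img0 <- render_glyph_patch(glyph_grid(as.character(1:9), offset_lr = c(0, 0)))
  diffpix <- which(unclass(img1) != unclass(img0), arr.ind = TRUE)
  expect_gt(nrow(diffpix), 0)
  expect_true(all(diffpix[, 1] > 160 & diffpix[, 2] > 160))

  # blank grid renders to an all-zero field
  blank <- render_glyph_patch(glyph_grid(rep(" ", 9)))
  expect_equal(sum(blank), 0)
})

test_that("unknown glyph ids are rejected by name", {
  expect_error(glyph_grid(c(as.character(1:8), "@")), "@")
  expect_error(glyph_grid(as.character(1:8)), "9 slots")
})

test_that("all embedded glyph bitmaps are pairwise distinct", {
  ids <- c(as.character(0:9), LETTERS)
  bms <- lapply(ids, svcnet:::glyph_bitmap)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      expect_true(any(bms[[i]] != bms[[j]]),
                  info = paste(ids[i], "vs", ids[j]))
    }
  }
})

test_that("natural-like generator is seeded, bounded, and 1/f-shaped", {
  a <- make_natural_like(1)
  b <- make_natural_like(1)
  expect_identical(unclass(a), unclass(b))
  expect_gte(min(a), 0)
  expect_lte(max(a), 1)
  expect_false(identical(unclass(a), unclass(make_natural_like(2))))
  expect_error(make_natural_like(1, size = -4), "positive")

  # radially averaged power spectrum decreases with frequency for exponent 1
  radial_power <- function(img) {
    px <- unclass(img) - mean(img)
    p <- Mod(stats::fft(px))^2
    n <- nrow(px)
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    rad <- sqrt(outer(k^2, k^2, "+"))
    bins <- cut(as.numeric(rad), breaks = c(0.01, 0.05, 0.1, 0.2, 0.45))
    tapply(as.numeric(p), bins, mean)
  }
  pw <- radial_power(a)
  expect_true(all(diff(pw) < 0))
  # white noise (exponent 0) has a flat spectrum by comparison
  pw0 <- radial_power(make_natural_like(1, spectrum_exponent = 0))
  expect_lt(max(pw0) / min(pw0), 3)
})

test_that("image io round-trips through PNG and PGM at 8-bit precision", {
  img <- render_glyph_patch(glyph_grid(as.character(1:9)))
  for (ext in c("png", "pgm")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_image(img, f)
    back <- read_image(f)
    expect_lte(max(abs(unclass(back) - unclass(img))), 1 / 255)
    unlink(f)
  }
})

test_that("io errors are specific and colour input becomes luminance", {
  expect_error(read_image(tempfile(fileext = ".png")), "not found")
  f <- tempfile(fileext = ".tif")
  file.create(f)
  expect_error(read_image(f), "unsupported")
  unlink(f)

  rgb <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  f <- tempfile(fileext = ".png")
  png::writePNG(rgb, f)
  lum <- read_image(f)
  expect_true(is.matrix(unclass(lum)))
  expect_gte(min(lum), 0)
  expect_lte(max(lum), 1)
  ref <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  expect_lt(max(abs(unclass(lum) - ref)), 2 / 255)
  unlink(f)
})

test_that("scene specifications validate quadrants", {
  p <- render_glyph_patch(glyph_grid(as.character(1:9)))
  expect_error(scene_spec(list()), "at least one")
  expect_error(scene_spec(list(XX = p)), "UL/UR/LL/LR")
  sc <- scene_spec(list(UL = p), name = "one")
  expect_s3_class(sc, "scene_spec")
})
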