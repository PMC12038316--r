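test_that("gaze quadrants tile the scene frame bijectively", {
  offs <- lapply(c("UL", "UR", "LL", "LR"),
                 function(q) gaze_direction(q)$offset)
  expect_equal(sort(sapply(offs, paste, collapse = ",")),
               sort(c("0,0", "0,16", "16,0", "16,16")))
  expect_error(gaze_direction("XX"), "invalid gaze")
  expect_equal(gaze_direction("UL")$angle,
               c(azimuth = -35, elevation = 35))
})

test_that("gaze remapping halves the patch into its quadrant", {
  set.seed(31)
  r <- matrix(runif(1024), 32, 32)
  ul <- remap_by_gaze(r, "UL")
  # support confined to the quadrant
  expect_true(all(ul[17:32, ] == 0) && all(ul[, 17:32] == 0))
  # total activity conserved up to the 2x2 averaging factor
  expect_equal(sum(ul), sum(r) / 4)
  # same rates under different gazes occupy disjoint supports
  ur <- remap_by_gaze(r, "UR")
  expect_equal(sum(ul > 0 & ur > 0), 0L)
  # block-average oracle for one cell
  expect_equal(ul[1, 1], mean(r[1:2, 1:2]))
  expect_error(remap_by_gaze(matrix(1, 16, 16), "UL"), "32x32")
})

test_that("attractor learning is symmetric, distance-weighted, and gated by rates", {
  rw <- recurrent_weights(sigma_d = 4)
  y <- matrix(0, 32, 32)
  y[10, 10] <- 1; y[10, 11] <- 1; y[10, 15] <- 1
  rw2 <- ca_update(rw, y, alpha = 0.1)
  expect_equal(rw2$W, t(rw2$W))
  expect_equal(sum(diag(rw2$W)), 0)
  expect_gte(min(rw2$W), 0)
  # silent neuron rows/columns untouched
  i_silent <- which(as.numeric(y) == 0)[1]
  expect_equal(sum(rw2$W[i_silent, ]), 0)
  # equal rates: the pair at distance 1 strengthens more than at distance 5
  i0 <- 10L + 9L * 32L; i1 <- 10L + 10L * 32L; i5 <- 10L + 14L * 32L
  expect_gt(rw2$W[i0, i1], rw2$W[i0, i5])
  expect_gt(rw2$W[i0, i5], 0)
  expect_error(recurrent_weights(sigma_d = -1), "positive")
})

test_that("recall with zero weights returns the thresholded cue", {
  rw0 <- recurrent_weights()
  set.seed(32)
  cue <- pmax(rnorm(1024), 0)
  rec <- ca_recall(rw0, cue, n_iter = 1, a_target = 0.05)
  ref <- set_sparseness(cue + 0 * cue, 0.05)$y
  expect_equal(as.numeric(rec$y) / max(rec$y), ref / max(ref))
  expect_equal(rec$a, 0.05, tolerance = 1e-3)
  expect_warning(deg <- ca_recall(rw0, numeric(1024)), "degenerate")
  expect_true(deg$degenerate)
})

test_that("a noisy half-amplitude cue recalls the stored pattern", {
  model <- alpha_model()
  scene <- alpha_scene()
  pat <- as.numeric(present(model, scene$patches$UL, "UL")$y3)
  pat <- pat / max(pat)
  set.seed(33)
  cue <- 0.5 * pat + abs(rnorm(1024, 0, 0.05))
  rec <- ca_recall(model$rw, cue, n_iter = 20, a_target = sparseness(pat))
  cosine <- sum(rec$y * pat) / sqrt(sum(rec$y^2) * sum(pat^2))
  expect_gte(cosine, 0.8)
  # recall sparseness is held at the target every run
  expect_equal(rec$a, sparseness(pat), tolerance = 1e-3)
})

test_that("bump centroids are rate-weighted means", {
  m <- matrix(0, 32, 32); m[5, 7] <- 2
  expect_equal(bump_centroid(m), c(row = 5, col = 7))
  m2 <- matrix(0, 32, 32); m2[1, 1] <- 1; m2[1, 11] <- 1
  expect_equal(bump_centroid(m2), c(row = 1, col = 6))
  # symmetric bump about (16.5, 16.5)
  g <- exp(-(outer((1:32 - 16.5)^2, (1:32 - 16.5)^2, "+")) / 8)
  expect_equal(bump_centroid(g), c(row = 16.5, col = 16.5), tolerance = 0.1)
  expect_error(bump_centroid(matrix(0, 4, 4)), "no centroid")
})

test_that("rates stay non-negative along a bump trajectory", {
  model <- alpha_model()
  init <- present(model, alpha_scene()$patches$UL, "UL")$y3
  relaxed <- ca_recall(model$rw, init, n_iter = 10, a_target = 0.02)$y
  traj <- bump_dynamics(model$rw, relaxed, adaptation_state(0.9, 1.0),
                        T = 30, a_target = 0.02)
  expect_true(all(vapply(traj$rates, function(m) min(m) >= 0, logical(1))))
  expect_equal(dim(traj$centroid), c(30L, 2L))
})
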