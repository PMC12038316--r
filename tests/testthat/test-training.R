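test_that("model building is deterministic in the master seed", {
  m1 <- build_model(config_alphanumeric_demo(), seed = 7L)
  m2 <- build_model(config_alphanumeric_demo(), seed = 7L)
  expect_identical(m1$conn[[1]]$idx, m2$conn[[1]]$idx)
  expect_identical(m1$conn[[2]]$w, m2$conn[[2]]$w)
  m3 <- build_model(config_alphanumeric_demo(), seed = 8L)
  expect_false(identical(m1$conn[[1]]$idx, m3$conn[[1]]$idx))
  # architecture defaults carried through
  expect_equal(ncol(m1$conn[[1]]$idx), 54L)
  expect_equal(ncol(m1$conn[[2]]$idx), 40L)
  expect_equal(m1$layers[[3]]$sparseness, 0.08)
})

test_that("training is reproducible and keeps weight norms at one", {
  scene <- alpha_scene()
  sched <- training_schedule(n_epochs = 2L, seed = 3L)
  t1 <- suppressMessages(train(build_model(config_alphanumeric_demo(), 5L),
                               scene, sched))
  t2 <- suppressMessages(train(build_model(config_alphanumeric_demo(), 5L),
                               scene, sched))
  for (l in 1:3) expect_identical(t1$conn[[l]]$w, t2$conn[[l]]$w)
  expect_identical(t1$rw$W, t2$rw$W)
  for (l in 1:3) {
    expect_equal(sqrt(rowSums(t1$conn[[l]]$w^2)), rep(1, 1024L),
                 tolerance = 1e-9)
  }
  expect_s3_class(t1$log, "data.frame")
  expect_true(all(c("stage", "epoch", "patch", "sparseness") %in%
                    names(t1$log)))
})

test_that("a black image propagates to zero rates in every layer", {
  model <- alpha_model()
  dark <- gray_image(matrix(0, 256, 256))
  out <- present(model, dark, "UL")
  expect_equal(sum(out$y1), 0)
  expect_equal(sum(out$y2), 0)
  expect_equal(sum(out$y3), 0)
})

test_that("presentation is pure and repeatable", {
  model <- alpha_model()
  img <- alpha_scene()$patches$UL
  o1 <- present(model, img, "UL")
  o2 <- present(model, img, "UL")
  expect_identical(o1$y1, o2$y1)
  expect_identical(o1$y3, o2$y3)
  expect_error(present(model, gray_image(matrix(0, 64, 64)), "UL"), "256x256")
})

test_that("trained layers respond to their patches at the trained gaze", {
  model <- alpha_model()
  scene <- alpha_scene()
  for (q in names(scene$patches)) {
    out <- present(model, scene$patches[[q]], q)
    expect_gt(sum(out$y1 > 0), 0)
    expect_gt(sum(out$y2 > 0), 0)
    expect_gt(sum(out$y3 > 0), 0)
  }
})

test_that("scene-layer responses stay inside the gaze quadrant", {
  model <- alpha_model()
  scene <- alpha_scene()
  quad_rows <- list(UL = 1:16, UR = 1:16)
  quad_cols <- list(UL = 1:16, UR = 17:32)
  for (q in c("UL", "UR")) {
    act <- which(present(model, scene$patches[[q]], q)$y3 > 0, arr.ind = TRUE)
    in_quad <- act[, 1] %in% quad_rows[[q]] & act[, 2] %in% quad_cols[[q]]
    expect_gte(mean(in_quad), 0.9)
    # stragglers sit within the connectivity radius of the quadrant border
    margin <- 2L
    near <- act[, 1] %in% range_pad(quad_rows[[q]], margin) &
      act[, 2] %in% range_pad(quad_cols[[q]], margin)
    expect_true(all(near))
  }
})

test_that("patch selectivity survives to the scene layer", {
  model <- alpha_model()
  scene <- alpha_scene()
  a_ul <- active_set(present(model, scene$patches$UL, "UL")$y3)
  a_ur <- active_set(present(model, scene$patches$UR, "UR")$y3)
  inactive <- mean(!(a_ul %in% a_ur))
  expect_gte(inactive, 0.9)
})

test_that("an empty scene is rejected and jittered training runs", {
  model <- build_model(config_alphanumeric_demo(), seed = 2L)
  expect_error(train(model, structure(list(patches = list(), name = "x"),
                                      class = "scene_spec")),
               "empty scene")
  small_sched <- training_schedule(n_epochs = 1L, n_update = 1L,
                                   n_buildup = 1L, seed = 1L)
  sc <- scene_spec(list(UL = alpha_scene()$patches$UL))
  tj <- suppressMessages(train(model, sc, small_sched, jitter_px = 4L))
  expect_s3_class(tj, "svc_model")
})

test_that("model archives round-trip through the columnar format", {
  model <- alpha_model()
  dir <- tempfile("archive")
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "connectivity_l1.csv")))
  back <- load_model(dir)
  for (l in 1:3) {
    expect_identical(back$conn[[l]]$idx, model$conn[[l]]$idx)
    expect_equal(back$conn[[l]]$w, model$conn[[l]]$w, tolerance = 1e-12)
  }
  expect_equal(back$rw$W, model$rw$W, tolerance = 1e-12)
  # a forward pass through the restored model matches the original
  img <- alpha_scene()$patches$UL
  expect_equal(present(back, img, "UL")$y3, present(model, img, "UL")$y3,
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
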