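test_that("sparseness matches its closed forms", {
  expect_equal(sparseness(c(1, 1, 0, 0)), 0.5)    # binary: k/n
  expect_equal(sparseness(rep(3.7, 12)), 1)       # uniform positive rates
  expect_equal(sparseness(c(3, 1, 0, 0)), 0.4)    # direct evaluation
  expect_equal(sparseness(numeric(8)), 0)         # all-zero convention
  # scale invariance and binary identity on random cases
  set.seed(21)
  for (i in 1:20) {
    y <- rpois(64, 2) * runif(64)
    expect_equal(sparseness(2.5 * y), sparseness(y))
    b <- as.numeric(runif(64) < 0.3)
    if (sum(b) > 0) expect_equal(sparseness(b), mean(b))
  }
})

test_that("threshold setting hits the target sparseness on random maps", {
  set.seed(22)
  for (a_target in c(0.1, 0.12, 0.08)) {
    for (i in 1:100) {
      h <- matrix(rnorm(1024), 32, 32)
      res <- set_sparseness(h, a_target)
      expect_lte(abs(res$a - a_target), 1e-3)
      expect_true(res$achieved)
      expect_gte(min(res$y), 0)
      expect_equal(res$y, pmax(matrix(h, 32, 32) - res$theta, 0))
    }
  }
})

test_that("threshold setting resolves the worked four-neuron example", {
  res <- set_sparseness(c(2, 1, 1, 1), 0.25)
  expect_equal(res$theta, 1, tolerance = 1e-6)
  expect_equal(res$a, 0.25, tolerance = 1e-3)
  expect_equal(res$y > 0, c(TRUE, FALSE, FALSE, FALSE))
  # identity case: the target equals the sparseness of the plain rectified map
  h <- c(0.5, 2, 0, 1.5)
  a0 <- sparseness(pmax(0, h))
  res0 <- set_sparseness(h, a0)
  expect_equal(res0$theta, 0, tolerance = 1e-6)
  expect_error(set_sparseness(h, 0), "\\(0, 1\\]")
  res_c <- set_sparseness(rep(2, 9), 0.5)
  expect_true(res_c$constant)
  expect_false(res_c$achieved)
  expect_equal(sum(res_c$y), 0)
})

test_that("the Mexican-hat filter is zero-sum with a centre-surround impulse response", {
  k <- svcnet:::dog_kernel(0.2, 1.5)
  expect_lt(abs(sum(k)), 1e-10)
  # uniform input is annihilated
  expect_lt(max(abs(lateral_inhibit(matrix(5, 32, 32)))), 1e-10)
  # single active neuron: positive centre, negative surround
  imp <- matrix(0, 32, 32); imp[16, 16] <- 1
  out <- lateral_inhibit(imp)
  expect_gt(out[16, 16], 0)
  expect_lt(out[16, 19], 0)
  expect_equal(out[16, 16], max(out))
  expect_error(lateral_inhibit(imp, 1.5, 0.2), "center_radius < surround")
})

test_that("activation is the afferent inner product", {
  # brute-force oracle over a small hand-built connectivity
  set.seed(23)
  idx <- matrix(sample.int(64L, 9L * 5L, TRUE), 9L, 5L)
  w <- matrix(runif(45), 9L, 5L)
  conn <- structure(list(idx = idx, w = w, source_dims = c(8L, 8L),
                         dims = c(3L, 3L)), class = "connectivity_map")
  x <- runif(64)
  h <- activate(conn, x)
  brute <- sapply(1:9, function(i) sum(w[i, ] * x[idx[i, ]]))
  expect_equal(as.numeric(h), brute)
  # zero input, and a single unit-weight afferent
  expect_equal(max(abs(activate(conn, numeric(64)))), 0)
  conn1 <- structure(list(idx = matrix(3L), w = matrix(1),
                          source_dims = c(4L, 1L), dims = c(1L, 1L)),
                     class = "connectivity_map")
  expect_equal(as.numeric(activate(conn1, c(0, 0, 0.7, 0))), 0.7)
  expect_error(activate(conn, runif(10)), "source dimensions")
})

test_that("the Hebbian update scales with the rate and renormalises", {
  set.seed(24)
  idx <- matrix(sample.int(64L, 8L * 3L, TRUE), 8L, 3L)
  conn <- structure(list(idx = idx,
                         w = matrix(runif(24), 8L, 3L),
                         source_dims = c(8L, 8L), dims = c(4L, 2L)),
                    class = "connectivity_map")
  conn$w <- conn$w / sqrt(rowSums(conn$w^2))
  x <- matrix(runif(24), 8L, 3L)
  y <- c(0, runif(7))
  upd <- hebb_update(conn, x, y, alpha = 0.5)
  # silent neuron keeps its weights exactly
  expect_identical(upd$w[1, ], conn$w[1, ])
  # every weight vector stays unit norm
  expect_equal(sqrt(rowSums(upd$w^2)), rep(1, 8L), tolerance = 1e-12)
  # pre-normalisation increment is alpha * y * x
  raw <- conn$w[2, ] + 0.5 * y[2] * x[2, ]
  expect_equal(upd$w[2, ], raw / sqrt(sum(raw^2)))
})

test_that("the trace recursion matches its closed-form geometric sum", {
  set.seed(25)
  eta <- 0.8
  ys <- lapply(1:100, function(i) matrix(runif(16), 4, 4))
  ybar <- 0
  for (t in 1:100) ybar <- trace_step(ybar, ys[[t]], eta)
  closed <- Reduce(`+`, Map(function(y, k) (1 - eta) * eta^k * y,
                            rev(ys), 0:99))
  expect_equal(ybar, closed, tolerance = 1e-12)
  # eta = 0: the trace is the instantaneous rate
  expect_identical(trace_step(matrix(5, 2, 2), matrix(1, 2, 2), 0),
                   matrix(1, 2, 2))
  expect_equal(trace_step(0, 1, 0.8), 0.2)
  # constant rates: geometric approach to the fixed point
  yb <- 0
  for (t in 1:60) yb <- trace_step(yb, 1, 0.8)
  expect_equal(yb, 1, tolerance = 1e-5)
})

test_that("the trace rule with eta = 0 is bit-identical to the Hebbian rule", {
  set.seed(26)
  idx <- matrix(sample.int(100L, 8L * 4L, TRUE), 8L, 4L)
  conn <- structure(list(idx = idx, w = matrix(runif(32), 8L, 4L),
                         source_dims = c(10L, 10L), dims = c(4L, 2L)),
                    class = "connectivity_map")
  conn$w <- conn$w / sqrt(rowSums(conn$w^2))
  x <- matrix(runif(32), 8L, 4L)
  y <- runif(8)
  ybar <- trace_step(0, y, 0)
  expect_identical(trace_update(conn, x, ybar, 0.3)$w,
                   hebb_update(conn, x, y, 0.3)$w)
  # zero trace leaves the weights untouched
  expect_identical(trace_update(conn, x, numeric(8), 0.3)$w, conn$w)
})
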