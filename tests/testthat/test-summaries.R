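# brute-force double-sum K oracle sharing only the definition, not the code
brute_k <- function(p, r, ngrid = 512) {
  A <- window_area(p$window)
  n <- p$n
  e <- matrix(0, n, n); dd <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    dx <- p$x[j] - p$x[i]; dy <- p$y[j] - p$y[i]
    dd[i, j] <- sqrt(dx^2 + dy^2)
    e[i, j] <- A / set_covariance(p$window, c(dx, dy), ngrid = ngrid)
  }
  vapply(r, function(rr) sum(e[dd <= rr]) * A / (n * (n - 1)), 0)
}

test_that("K on two points matches the hand oracle", {
  w <- unit_sq()
  p <- point_pattern(c(0.25, 0.75), c(0.5, 0.5), w)
  r <- c(0, 0.2, 0.4, 0.49, 0.5, 0.6)
  est <- suppressWarnings(k_translation(p, r = r)$est)
  # each ordered pair weight |W|/setcov = 1/0.5 = 2; A/(n(n-1)) * 4 = 2
  expect_equal(est, brute_k(p, r))
  expect_equal(est, c(0, 0, 0, 0, 2, 2))
  expect_equal(est[1], 0)   # K(0) = 0 always
})

test_that("K matches the brute-force double sum on a rectangle pattern", {
  w <- win_rect(c(0, 5), c(0, 4))
  p <- csr_pattern(w, 1.2, seed = 21)
  r <- seq(0, 1, length.out = 21)
  expect_equal(k_translation(p, r = r)$est, brute_k(p, r), tolerance = 1e-10)
})

test_that("K properties: monotone, zero without close pairs, translation invariant", {
  w <- win_rect(c(0, 10), c(0, 10))
  for (s in 1:5) {
    p <- csr_pattern(w, 0.8, seed = 400 + s)
    k <- k_translation(p, nr = 65)
    expect_true(all(diff(k$est) >= -1e-12))
    expect_equal(k$est[1], 0)
    # rigid translation of pattern + window
    w2 <- win_rect(c(0, 10) + 3.5, c(0, 10) - 2)
    p2 <- point_pattern(p$x + 3.5, p$y - 2, w2)
    expect_equal(k_translation(p2, nr = 65)$est, k$est)
  }
  # pattern with no pair closer than r_max has K identically zero
  grid_pts <- expand.grid(x = seq(1, 9, by = 4), y = seq(1, 9, by = 4))
  sparse <- point_pattern(grid_pts$x, grid_pts$y, w)
  expect_true(all(k_translation(sparse, r = seq(0, 2.5, length.out = 33))$est == 0))
})

test_that("L transform and its closed forms", {
  w <- m1_window()
  p <- csr_pattern(w, 1, seed = 23)
  k <- k_translation(p, nr = 65)
  # CSR identity case: plug the theoretical curve through the transform
  k_theo <- k; k_theo$est <- pi * k$r^2
  expect_equal(l_from_k(k_theo)$est, k$r)
  k_zero <- k; k_zero$est <- rep(0, length(k$r))
  expect_true(all(l_from_k(k_zero)$est == 0))
  k1 <- k; k1$est <- rep(1, length(k$r))
  expect_equal(l_from_k(k1)$est[5], sqrt(1 / pi), tolerance = 1e-12)
  expect_equal(l_translation(p, nr = 65)$est, sqrt(pmax(k$est, 0) / pi))
})

test_that("pcf equals an independent brute-force kernel double sum to 1e-10", {
  w <- win_rect(c(0, 5), c(0, 4))
  set.seed(25)
  p <- point_pattern(uniform_points(w, 20), window = w)
  r <- seq(0, 1, length.out = 41)
  b <- 0.2
  g <- pair_correlation(p, r = r, bandwidth = b)$est
  A <- window_area(w); n <- p$n
  acc <- numeric(length(r))
  for (i in 1:n) for (j in 1:n) if (i != j) {
    dx <- p$x[j] - p$x[i]; dy <- p$y[j] - p$y[i]
    d <- sqrt(dx^2 + dy^2)
    e <- A / ((5 - abs(dx)) * (4 - abs(dy)))
    u <- (r - d) / b
    acc <- acc + 0.75 / b * pmax(1 - u^2, 0) * e / d
  }
  oracle <- acc * A / (2 * pi * n * (n - 1))
  expect_equal(g, oracle, tolerance = 1e-10)
})

test_that("pcf detects aggregation in a pair-clustered pattern", {
  w <- m1_window()
  set.seed(26)
  p <- simulate_model(pair_process(73 / (1.75 * 80), 0.28, 0.75), w)
  g <- pair_correlation(p, r = seq(0, 1, length.out = 101))
  expect_gt(g$est[which.min(abs(g$r - 0.15))], 1)
  expect_true(any(g$boundary_affected))
})

test_that("pcf is calibrated under CSR (mean near 1 at r = 1)", {
  w <- win_rect(c(0, 10), c(0, 10))
  set.seed(27)
  gm <- replicate(100, {
    p <- csr_pattern(w, 1, seed = NULL)
    pair_correlation(p, r = c(0, 0.5, 1.0))$est[3]
  })
  expect_lt(abs(mean(gm) - 1) / (sd(gm) / sqrt(length(gm))), 3)
})
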