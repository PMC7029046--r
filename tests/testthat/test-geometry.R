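test_that("window areas: rectangles, abutting-sheet polygons, holes", {
  expect_equal(window_area(unit_sq()), 1.0)
  # two abutting 2 m x 6 m survey sheets traced as one outline: 24 m^2
  m2 <- win_poly(cbind(c(0, 6, 6, 6, 0, 0), c(0, 0, 2, 4, 4, 2)))
  expect_equal(window_area(m2), 24.0)
  expect_equal(window_area(holed_sq()), 3.0)
  # polygonised rectangle equals the closed form to machine precision
  r <- win_poly(cbind(c(0, 3.7, 3.7, 0), c(0, 0, 1.9, 1.9)))
  expect_equal(window_area(r), 3.7 * 1.9)
})

test_that("invalid geometry is rejected", {
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(win_poly(bowtie), "self-intersecting")
  expect_error(win_poly(cbind(c(0, 1), c(0, 1))), "3")
  # hole outside the outer polygon
  expect_error(win_poly(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                        list(cbind(c(2, 3, 3, 2), c(2, 2, 3, 3)))))
})

test_that("containment follows the boundary convention", {
  expect_true(contains(unit_sq(), 0.5, 0.5))
  expect_false(contains(holed_sq(), 1.0, 1.0))   # hole centre
  expect_true(contains(unit_sq(), 0, 0.5))       # outer boundary inside
  expect_false(contains(holed_sq(), 0.5, 1.0))   # hole boundary outside
})

test_that("containment agrees with an independent winding-number oracle", {
  w <- two_hole_poly()
  set.seed(101)
  px <- runif(1000, -0.5, 6.5); py <- runif(1000, -0.5, 4.5)
  oracle <- winding_inside(w$outer, px, py)
  for (h in w$holes) oracle <- oracle & !winding_inside(h, px, py)
  expect_identical(contains(w, px, py), oracle)
})

test_that("set covariance: closed form, identity, symmetry, raster accuracy", {
  expect_equal(set_covariance(unit_sq(), c(0.5, 0)), 0.5)
  w <- two_hole_poly()
  expect_equal(set_covariance(w, c(0, 0), ngrid = 512), window_area(w),
               tolerance = 0.01)
  expect_equal(set_covariance(unit_sq(), c(2, 0)), 0)  # degenerate shift
  set.seed(7)
  for (i in 1:5) {
    s <- runif(2, -0.5, 0.5)
    expect_equal(set_covariance(w, s, ngrid = 256),
                 set_covariance(w, -s, ngrid = 256), tolerance = 1e-6)
  }
  # rectangle-as-polygon raster matches the closed form within 1%
  rp <- win_poly(cbind(c(0, 4, 4, 0), c(0, 0, 3, 3)))
  for (s in list(c(0.8, 0.4), c(-1.2, 0.9), c(0.3, -1.1))) {
    expect_equal(set_covariance(rp, s, ngrid = 512),
                 (4 - abs(s[1])) * (3 - abs(s[2])), tolerance = 0.01)
  }
})

test_that("polygon-with-hole set covariance matches a Monte-Carlo oracle within 1%", {
  w <- two_hole_poly()
  set.seed(8)
  px <- runif(2e5, 0, 6); py <- runif(2e5, 0, 4)
  mc <- mean(contains(w, px, py) & contains(w, px - 0.3, py - 0.2)) * 24
  expect_equal(set_covariance(w, c(0.3, 0.2), ngrid = 1024), mc,
               tolerance = 0.01)
})

test_that("cached FFT set-covariance interpolator matches direct raster evaluation", {
  w <- two_hole_poly()
  f <- bedplane:::setcov_interp(w, 256)
  set.seed(12)
  for (i in 1:8) {
    s <- runif(2, -1, 1)
    expect_equal(f(s[1], s[2]), set_covariance(w, s, ngrid = 512),
                 tolerance = 0.02)
  }
})

test_that("uniform points: count, containment, uniformity", {
  expect_equal(nrow(uniform_points(unit_sq(), 0)), 0)
  w <- two_hole_poly()
  pts <- uniform_points(w, 500, seed = 3)
  expect_equal(nrow(pts), 500)
  expect_true(all(contains(w, pts)))
  # chi-square on quadrant counts of 10000 points in the unit square
  q <- uniform_points(unit_sq(), 10000, seed = 4)
  cnt <- table(cut(q[, 1], c(0, 0.5, 1), include.lowest = TRUE),
               cut(q[, 2], c(0, 0.5, 1), include.lowest = TRUE))
  expect_gt(suppressWarnings(chisq.test(cnt)$p.value), 0.001)
})

test_that("GeoJSON round trip preserves the window", {
  w <- two_hole_poly()
  f <- tempfile(fileext = ".geojson")
  write_window_geojson(w, f)
  w2 <- read_window_geojson(f)
  expect_equal(window_area(w2), window_area(w))
  set.seed(5)
  px <- runif(200, 0, 6); py <- runif(200, 0, 4)
  expect_identical(contains(w2, px, py), contains(w, px, py))
})
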