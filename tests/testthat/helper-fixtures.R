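# shared fixtures: small windows and patterns built in code

unit_sq <- function() win_rect(c(0, 1), c(0, 1))

# 2x2 square with a centred 1x1 hole (area 3)
holed_sq <- function() {
  win_poly(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)),
           list(cbind(c(0.5, 1.5, 1.5, 0.5), c(0.5, 0.5, 1.5, 1.5))))
}

# M1-sized rectangle, 8 x 10 m = 80 m^2
m1_window <- function() win_rect(c(0, 8), c(0, 10))

# irregular polygon window with two holes, used for raster-oracle checks
two_hole_poly <- function() {
  win_poly(cbind(c(0, 6, 6, 0), c(0, 0, 4, 4)),
           list(cbind(c(1, 2, 2, 1), c(1, 1, 2, 2)),
                cbind(c(4, 5, 5, 4), c(2.5, 2.5, 3.2, 3.2))))
}

csr_pattern <- function(w, lambda, seed) {
  if (!is.null(seed)) set.seed(seed)
  p <- simulate_model(hom_poisson(lambda), w)
  while (p$n < 2) p <- simulate_model(hom_poisson(lambda), w)
  p
}

# independent winding-number point-in-polygon oracle (different algorithm
# from the even-odd ray casting used by the implementation)
winding_inside <- function(ring, px, py) {
  n <- nrow(ring)
  wn <- numeric(length(px))
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    j <- if (k == n) 1 else k + 1
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    isleft <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    up <- y1 <= py & y2 > py & isleft > 0
    dn <- y1 > py & y2 <= py & isleft < 0
    wn <- wn + up - dn
  }
  wn != 0
}
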