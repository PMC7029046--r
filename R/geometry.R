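#' Observation windows
#'
#' A window is the planar region on which a point pattern was observed: an
#' outer polygon, optionally minus a set of hole polygons ("gaps" where no
#' observation was possible, e.g. sediment cover on a bedding plane).
#' Coordinates are planar metres; the origin is arbitrary.
#'
#' @param xrange,yrange numeric length-2 vectors giving the rectangle extent.
#' @return an object of class `bp_window`.
#' @examples
#' w <- win_rect(c(0, 8), c(0, 10))
#' window_area(w)
#' @export
win_rect <- function(xrange, yrange) {
  stopifnot(length(xrange) == 2, length(yrange) == 2,
            diff(xrange) > 0, diff(yrange) > 0)
  outer <- cbind(x = c(xrange[1], xrange[2], xrange[2], xrange[1]),
                 y = c(yrange[1], yrange[1], yrange[2], yrange[2]))
  w <- structure(list(kind = "rectangle", outer = outer, holes = list(),
                      xrange = as.numeric(xrange), yrange = as.numeric(yrange),
                      cache = new.env(parent = emptyenv())),
                 class = "bp_window")
  w
}

#' Polygonal window with optional holes
#'
#' @param outer two-column matrix of vertices (not repeated at the end);
#'   either winding order is accepted.
#' @param holes list of two-column vertex matrices, each strictly inside
#'   `outer` and pairwise disjoint.
#' @export
win_poly <- function(outer, holes = list()) {
  outer <- check_ring(outer)
  holes <- lapply(holes, check_ring)
  a_outer <- ring_area(outer)
  a_holes <- vapply(holes, ring_area, 0)
  if (a_outer - sum(a_holes) <= 0)
    stop("window has non-positive area")
  w <- structure(list(kind = "polygon", outer = outer, holes = holes,
                      xrange = range(outer[, 1]), yrange = range(outer[, 2]),
                      cache = new.env(parent = emptyenv())),
                 class = "bp_window")
  for (i in seq_along(holes)) {
    ctr <- colMeans(holes[[i]])
    if (!ring_contains(outer, ctr[1], ctr[2]))
      stop("hole ", i, " is not inside the outer polygon")
  }
  w
}

# validate a ring: matrix, >= 3 vertices, no self intersection
check_ring <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2 || nrow(m) < 3) stop("a polygon ring needs >= 3 x,y vertices")
  # drop an explicitly closed last vertex
  if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3) stop("a polygon ring needs >= 3 distinct vertices")
  if (ring_self_intersects(m)) stop("invalid geometry: self-intersecting polygon")
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

# O(n^2) segment crossing test between non-adjacent edges
ring_self_intersects <- function(m) {
  n <- nrow(m)
  a <- m
  b <- m[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    # edge n is adjacent to edge 1
    if (i == 1) js <- js[js != n]
    if (!length(js)) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE], b[js, , drop = FALSE])))
      return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- sign((p2[1] - p1[1]) * (q1[, 2] - p1[2]) - (p2[2] - p1[2]) * (q1[, 1] - p1[1]))
  d2 <- sign((p2[1] - p1[1]) * (q2[, 2] - p1[2]) - (p2[2] - p1[2]) * (q2[, 1] - p1[1]))
  d3 <- sign((q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1]))
  d4 <- sign((q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1]))
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

ring_area <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1)
  abs(sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2])) / 2
}

#' Window area in square metres
#'
#' Hole areas are subtracted, so this is the area actually observable.
#' @param w a `bp_window`.
#' @export
window_area <- function(w) {
  stopifnot(inherits(w, "bp_window"))
  ring_area(w$outer) - sum(vapply(w$holes, ring_area, 0))
}

# even-odd ray casting for a single ring, boundary-inclusive
# vectorised over (px, py)
ring_contains <- function(ring, px, py, boundary = TRUE) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    # on-segment test
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    within <- px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
              py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | (abs(cr) < 1e-12 & within)
    crosses <- ((y1 > py) != (y2 > py)) &
               (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  if (boundary) inside | on_edge else inside & !on_edge
}

#' Point-in-window test
#'
#' Points on the outer boundary count as inside; points on a hole boundary
#' count as outside (so a point is "contained" only where observation was
#' possible).
#'
#' @param w a `bp_window`.
#' @param x,y coordinate vectors (or `x` a two-column matrix).
#' @return logical vector.
#' @export
contains <- function(w, x, y = NULL) {
  stopifnot(inherits(w, "bp_window"))
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  if (w$kind == "rectangle") {
    ok <- x >= w$xrange[1] & x <= w$xrange[2] &
          y >= w$yrange[1] & y <= w$yrange[2]
  } else {
    ok <- ring_contains(w$outer, x, y, boundary = TRUE)
  }
  for (h in w$holes) {
    ok <- ok & !ring_contains(h, x, y, boundary = TRUE)
  }
  ok
}

#' Uniform random points in a window
#'
#' Rejection sampling from the bounding box.
#' @param w a `bp_window`.
#' @param n number of points.
#' @param seed optional integer seed.
#' @return two-column matrix with exactly `n` rows.
#' @export
uniform_points <- function(w, n, seed = NULL) {
  stopifnot(inherits(w, "bp_window"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (window_area(w) <= 0) stop("cannot sample points from a zero-area window")
  out <- matrix(numeric(0), ncol = 2)
  bbarea <- diff(w$xrange) * diff(w$yrange)
  frac <- max(window_area(w) / bbarea, 1e-3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / frac) + 10
    px <- stats::runif(m, w$xrange[1], w$xrange[2])
    py <- stats::runif(m, w$yrange[1], w$yrange[2])
    keep <- contains(w, px, py)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Set covariance of a window
#'
#' `set_covariance(w, shift)` is the area of overlap between the window and a
#' translated copy of itself, the denominator of the translation edge
#' correction. Rectangles use the closed form (a-|dx|)(b-|dy|); polygons and
#' windows with holes are evaluated on a raster grid over the bounding box.
#'
#' @param w a `bp_window`.
#' @param shift numeric length-2 translation in metres.
#' @param ngrid raster resolution per axis for the polygon case.
#' @export
set_covariance <- function(w, shift, ngrid = 1024) {
  stopifnot(inherits(w, "bp_window"), length(shift) == 2)
  if (w$kind == "rectangle" && length(w$holes) == 0) {
    a <- diff(w$xrange); b <- diff(w$yrange)
    return(max(a - abs(shift[1]), 0) * max(b - abs(shift[2]), 0))
  }
  gx <- seq(w$xrange[1], w$xrange[2], length.out = ngrid)
  gy <- seq(w$yrange[1], w$yrange[2], length.out = ngrid)
  pts <- cbind(rep(gx, times = ngrid), rep(gy, each = ngrid))
  in1 <- contains(w, pts[, 1], pts[, 2])
  # average both shift directions so the raster estimate is exactly
  # symmetric in +/- shift, as the true set covariance is
  in2 <- contains(w, pts[, 1] - shift[1], pts[, 2] - shift[2])
  in3 <- contains(w, pts[, 1] + shift[1], pts[, 2] + shift[2])
  (mean(in1 & in2) + mean(in1 & in3)) / 2 * diff(w$xrange) * diff(w$yrange)
}

# binary inside-mask over the bounding box, cached on the window
window_mask <- function(w, dimyx = 256) {
  key <- paste0("mask", dimyx)
  if (!is.null(w$cache[[key]])) return(w$cache[[key]])
  gx <- seq(w$xrange[1], w$xrange[2], length.out = dimyx)
  gy <- seq(w$yrange[1], w$yrange[2], length.out = dimyx)
  m <- matrix(contains(w, rep(gx, each = dimyx), rep(gy, times = dimyx)),
              nrow = dimyx)           # m[iy, ix]
  res <- list(m = m, gx = gx, gy = gy,
              dx = gx[2] - gx[1], dy = gy[2] - gy[1])
  w$cache[[key]] <- res
  res
}

# set covariance image by FFT autocorrelation of the window mask, cached.
# Returns a function (dx, dy) -> covariance area via bilinear interpolation.
setcov_interp <- function(w, dimyx = 256) {
  key <- paste0("setcov", dimyx)
  if (!is.null(w$cache[[key]])) return(w$cache[[key]])
  msk <- window_mask(w, dimyx)
  m <- msk$m * 1
  pad <- matrix(0, 2 * dimyx, 2 * dimyx)
  pad[seq_len(dimyx), seq_len(dimyx)] <- m
  F <- stats::fft(pad)
  cc <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(pad)
  # cc[1 + s] = sum_k m[k] m[k + s] with wraparound; reorder to shifts
  # -(dimyx-1) .. (dimyx-1) on each axis
  idx <- c((dimyx + 2):(2 * dimyx), 1:dimyx)
  cc <- cc[idx, idx] * msk$dx * msk$dy
  shifts_y <- (-(dimyx - 1):(dimyx - 1)) * msk$dy
  shifts_x <- (-(dimyx - 1):(dimyx - 1)) * msk$dx
  f <- function(dx, dy) {
    ix <- findInterval(dx, shifts_x, all.inside = TRUE)
    iy <- findInterval(dy, shifts_y, all.inside = TRUE)
    tx <- (dx - shifts_x[ix]) / msk$dx
    ty <- (dy - shifts_y[iy]) / msk$dy
    v <- cc[cbind(iy, ix)] * (1 - tx) * (1 - ty) +
         cc[cbind(iy, ix + 1)] * tx * (1 - ty) +
         cc[cbind(iy + 1, ix)] * (1 - tx) * ty +
         cc[cbind(iy + 1, ix + 1)] * tx * ty
    pmax(v, msk$dx * msk$dy)  # clip at one pixel to keep weights finite
  }
  w$cache[[key]] <- f
  f
}

# translation-correction weights |W| / |W n W_shifted| for pair displacements
translation_weights <- function(w, dx, dy, dimyx = 256) {
  A <- window_area(w)
  if (w$kind == "rectangle" && length(w$holes) == 0) {
    a <- diff(w$xrange); b <- diff(w$yrange)
    denom <- pmax(a - abs(dx), 0) * pmax(b - abs(dy), 0)
    denom <- pmax(denom, .Machine$double.eps)
  } else {
    denom <- setcov_interp(w, dimyx)(dx, dy)
  }
  A / denom
}

#' @export
print.bp_window <- function(x, ...) {
  cat(sprintf("window (%s): [%g, %g] x [%g, %g] m, %d hole(s), area %.4g m^2\n",
              x$kind, x$xrange[1], x$xrange[2], x$yrange[1], x$yrange[2],
              length(x$holes), window_area(x)))
  invisible(x)
}

#' Read / write a window as GeoJSON
#'
#' The window is stored as a single GeoJSON Polygon: first ring outer,
#' subsequent rings holes, coordinates in metres. Ring orientation is
#' normalised on read.
#' @param path file path.
#' @rdname window_geojson
#' @export
read_window_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(g$type) && g$type == "Feature") g <- g$geometry
  if (is.null(g$type) || g$type != "Polygon")
    stop("expected a GeoJSON Polygon")
  rings <- g$coordinates
  if (is.array(rings)) rings <- lapply(seq_len(dim(rings)[1]), function(i) rings[i, , ])
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    r
  })
  win_poly(rings[[1]], rings[-1])
}

#' @param w a `bp_window`.
#' @rdname window_geojson
#' @export
write_window_geojson <- function(w, path) {
  close_ring <- function(m) rbind(m, m[1, ])
  coords <- c(list(close_ring(w$outer)), lapply(w$holes, close_ring))
  coords <- lapply(coords, function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2])))
  jsonlite::write_json(list(type = "Polygon", coordinates = coords),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
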