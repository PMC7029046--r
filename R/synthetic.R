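#' Synthetic bedding-plane scenes
#'
#' Generates marked multi-taxon patterns with the statistical structure the
#' analysis pipeline assumes: a pair-clustered oncocerid layer, a denser
#' spatially random ammonoid layer, a sparse near-random orthocerid layer,
#' unobservable gaps masking part of the surface, dispersed orientations,
#' symmetric widths and right-skewed lengths. Defaults approximate a
#' 73-point oncocerid layer on 80 m^2 with pair radius 0.28 m and pair
#' retention probability 0.75.
#'
#' @param window a rectangle window; default 8 m x 10 m.
#' @param oncocerid_n target expected oncocerid count before gap thinning.
#' @param pair_radius,pair_retention pair-process parameters r_c and P.
#' @param ammonoid_lambda,orthocerid_lambda layer intensities (points/m^2);
#'   set to 0 to drop a layer.
#' @param ammonoid_beta optional log-linear coefficients; when given the
#'   ammonoid layer is inhomogeneous Poisson instead of homogeneous.
#' @param gap_fraction target fraction of area masked by gaps, in [0, 0.5].
#' @param orientation "uniform" or "vonmises".
#' @param mu_dir,kappa_vm von Mises mean direction (deg) and concentration.
#' @param width_mean,width_sd truncated-normal width model (mm).
#' @param length_shape,length_scale Gamma length model (mm).
#' @param seed master seed; the whole scene is reproducible given it.
#' @return a `bp_scene_config` list.
#' @export
scene_config <- function(window = win_rect(c(0, 8), c(0, 10)),
                         oncocerid_n = 73,
                         pair_radius = 0.28, pair_retention = 0.75,
                         ammonoid_lambda = 3.42, ammonoid_beta = NULL,
                         orthocerid_lambda = 1.0,
                         gap_fraction = 0.09,
                         orientation = c("uniform", "vonmises"),
                         mu_dir = 301, kappa_vm = 0.5,
                         width_mean = 55, width_sd = 12,
                         length_shape = 3, length_scale = 31.3,
                         seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(gap_fraction >= 0, gap_fraction <= 0.5,
            oncocerid_n >= 0, ammonoid_lambda >= 0, orthocerid_lambda >= 0)
  structure(list(window = window, oncocerid_n = oncocerid_n,
                 pair_radius = pair_radius, pair_retention = pair_retention,
                 ammonoid_lambda = ammonoid_lambda, ammonoid_beta = ammonoid_beta,
                 orthocerid_lambda = orthocerid_lambda,
                 gap_fraction = gap_fraction, orientation = orientation,
                 mu_dir = mu_dir, kappa_vm = kappa_vm,
                 width_mean = width_mean, width_sd = width_sd,
                 length_shape = length_shape, length_scale = length_scale,
                 seed = as.integer(seed)),
            class = "bp_scene_config")
}

#' Random gap mask
#'
#' Removes random disc-shaped patches (24-gons) from a rectangular window
#' until the masked area is within one percentage point of the target
#' fraction. Gaps are pairwise disjoint and lie strictly inside the outer
#' boundary; they model surface patches where observation was impossible.
#'
#' @param w a rectangle `bp_window` without holes.
#' @param fraction target masked fraction in [0, 0.5].
#' @param seed optional integer seed.
#' @param max_tries placement retry cap.
#' @return a polygonal `bp_window` with holes (or `w` itself if
#'   `fraction == 0`).
#' @export
generate_gap_mask <- function(w, fraction, seed = NULL, max_tries = 5000) {
  stopifnot(inherits(w, "bp_window"), fraction >= 0, fraction <= 0.5)
  if (length(w$holes)) stop("window already has holes")
  if (fraction == 0) return(w)
  if (!is.null(seed)) set.seed(seed)
  A <- window_area(w)
  target <- fraction * A
  tol <- 0.01 * A                       # one percentage point of total area
  base_r <- sqrt(A) * c(0.03, 0.06)
  holes <- list()
  centres <- matrix(numeric(0), ncol = 3)  # x, y, r
  masked <- 0
  tries <- 0
  # iterate until well inside the tolerance band; the final disc is sized
  # to land the masked area on the target itself
  while (masked < target - 0.25 * tol) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not reach the target gap fraction after ", max_tries, " tries")
    r <- stats::runif(1, base_r[1], base_r[2])
    # size the last gap to land on the target, not its lower tolerance edge
    r <- min(r, sqrt((target - masked) / pi))
    if (r <= 0) break
    margin <- r + 0.02 * sqrt(A)
    if (w$xrange[2] - w$xrange[1] < 2 * margin ||
        w$yrange[2] - w$yrange[1] < 2 * margin) next
    cx <- stats::runif(1, w$xrange[1] + margin, w$xrange[2] - margin)
    cy <- stats::runif(1, w$yrange[1] + margin, w$yrange[2] - margin)
    if (nrow(centres) > 0) {
      dd <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
      if (any(dd < centres[, 3] + r + 0.01 * sqrt(A))) next
    }
    th <- seq(0, 2 * pi, length.out = 25)[-25]
    ring <- cbind(cx + r * cos(th), cy + r * sin(th))
    holes <- c(holes, list(ring))
    centres <- rbind(centres, c(cx, cy, r))
    masked <- masked + ring_area(ring)
  }
  if (abs(masked - target) > tol)
    stop("gap mask missed the target fraction")
  win_poly(w$outer, holes)
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm); degrees
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(f)
    th <- th[ok]
    take <- min(length(th), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  ((out + mu) * 180 / pi) %% 360
}

draw_marks <- function(n, taxon, cfg) {
  if (n == 0)
    return(data.frame(taxon = character(0), angle_deg = numeric(0),
                      length_mm = numeric(0), width_mm = numeric(0)))
  ang <- if (cfg$orientation == "uniform") stats::runif(n, 0, 360)
         else rvonmises_deg(n, cfg$mu_dir, cfg$kappa_vm)
  wid <- stats::rnorm(n, cfg$width_mean, cfg$width_sd)
  while (any(wid <= 0)) {
    bad <- wid <= 0
    wid[bad] <- stats::rnorm(sum(bad), cfg$width_mean, cfg$width_sd)
  }
  len <- stats::rgamma(n, shape = cfg$length_shape, scale = cfg$length_scale)
  data.frame(taxon = rep(taxon, n), angle_deg = ang,
             length_mm = len, width_mm = wid)
}

#' Generate a synthetic bedding-plane scene
#'
#' Draws the gap mask, then each taxon layer from its point-process model on
#' the gap-masked window (gaps thin points: a fossil under cover is
#' unobservable, not displaced), then attaches marks. Deterministic given
#' the config's master seed.
#'
#' @param cfg a [scene_config()].
#' @return a list of class `bp_scene` with elements `pattern` (marked
#'   `bp_pattern` on the gap-masked window) and `config`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "bp_scene_config"))
  set.seed(cfg$seed)
  w_full <- cfg$window
  A_full <- window_area(w_full)
  w <- generate_gap_mask(w_full, cfg$gap_fraction)
  layers <- list()
  if (cfg$oncocerid_n > 0) {
    kappa <- cfg$oncocerid_n / ((1 + cfg$pair_retention) * A_full)
    spec <- pair_process(kappa, cfg$pair_radius, cfg$pair_retention)
    layers$Oncocerida <- simulate_model(spec, w)
  }
  if (!is.null(cfg$ammonoid_beta)) {
    layers$Ammonoidea <- simulate_model(inhom_poisson(cfg$ammonoid_beta), w)
  } else if (cfg$ammonoid_lambda > 0) {
    layers$Ammonoidea <- simulate_model(hom_poisson(cfg$ammonoid_lambda), w)
  }
  if (cfg$orthocerid_lambda > 0) {
    layers$Orthocerida <- simulate_model(hom_poisson(cfg$orthocerid_lambda), w)
  }
  xs <- unlist(lapply(layers, function(p) p$x))
  ys <- unlist(lapply(layers, function(p) p$y))
  marks <- do.call(rbind, Map(function(p, taxon) draw_marks(p$n, taxon, cfg),
                              layers, names(layers)))
  rownames(marks) <- NULL
  pat <- point_pattern(xs, ys, w, marks = marks)
  structure(list(pattern = pat, config = cfg), class = "bp_scene")
}

#' @export
print.bp_scene <- function(x, ...) {
  cat("synthetic bedding-plane scene (seed ", x$config$seed, ")\n", sep = "")
  print(x$pattern)
  invisible(x)
}

#' Write a scene to disk
#'
#' Emits the pattern CSV, the window GeoJSON, and the resolved config as
#' JSON, under a common file stem.
#' @param scene a `bp_scene`.
#' @param stem path prefix for the three files.
#' @export
write_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "bp_scene"))
  write_pattern_csv(scene$pattern, paste0(stem, "_pattern.csv"))
  write_window_geojson(scene$pattern$window, paste0(stem, "_window.geojson"))
  cfg <- scene$config
  cfg$window <- list(xrange = cfg$window$xrange, yrange = cfg$window$yrange)
  jsonlite::write_json(unclass(cfg), paste0(stem, "_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}
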