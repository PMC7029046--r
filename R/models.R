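#' Point-process model specifications
#'
#' Four generative models for bedding-plane patterns:
#' * `hom_poisson(lambda)` — complete spatial randomness at constant
#'   intensity `lambda` (points / m^2).
#' * `inhom_poisson(beta)` — Poisson process with log-linear intensity
#'   `lambda(x, y) = exp(b0 + b1 x + b2 y)`.
#' * `thomas_process(kappa, sigma, mu)` — Neyman-Scott cluster process:
#'   Poisson parents at intensity `kappa`, each replaced by a
#'   Poisson(`mu`)-sized cluster of offspring displaced by an isotropic
#'   Gaussian with standard deviation `sigma` (implied intensity
#'   `kappa * mu`).
#' * `pair_process(kappa, r_c, p_ret)` — modified Gauss-Poisson pair
#'   process: Poisson parents at intensity `kappa`; each parent is replaced
#'   by two points placed independently and uniformly in the disc of radius
#'   `r_c` around it, one of which is deleted with probability
#'   `1 - p_ret` (implied intensity `kappa * (1 + p_ret)`).
#'
#' @param lambda,beta,kappa,sigma,mu,r_c,p_ret model parameters; see above.
#' @return an object of class `bp_model`.
#' @name models
NULL

#' @rdname models
#' @export
hom_poisson <- function(lambda) {
  stopifnot(lambda >= 0)
  structure(list(model = "hom_poisson", lambda = lambda), class = "bp_model")
}

#' @rdname models
#' @export
inhom_poisson <- function(beta) {
  stopifnot(length(beta) == 3, all(is.finite(beta)))
  structure(list(model = "inhom_poisson", beta = as.numeric(beta)),
            class = "bp_model")
}

#' @rdname models
#' @export
thomas_process <- function(kappa, sigma, mu) {
  stopifnot(kappa > 0, sigma > 0, mu >= 0)
  structure(list(model = "thomas", kappa = kappa, sigma = sigma, mu = mu),
            class = "bp_model")
}

#' @rdname models
#' @export
pair_process <- function(kappa, r_c, p_ret) {
  stopifnot(kappa > 0, r_c > 0, p_ret >= 0, p_ret <= 1)
  structure(list(model = "pair_process", kappa = kappa, r_c = r_c,
                 p_ret = p_ret), class = "bp_model")
}

implied_intensity <- function(spec) {
  switch(spec$model,
         hom_poisson = spec$lambda,
         thomas = spec$kappa * spec$mu,
         pair_process = spec$kappa * (1 + spec$p_ret),
         stop("no closed-form intensity for model ", spec$model))
}

#' @export
print.bp_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "model")]
  cat(x$model, ": ",
      paste(names(pars), signif(unlist(pars), 4), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a point pattern from a model
#'
#' Cluster-model parents are generated on the bounding box dilated by a
#' buffer (4 sigma for Thomas, the disc radius for the pair process) so that
#' clusters straddling the window edge are represented; offspring outside
#' the window are discarded. Counts are Poisson — simulations are not
#' conditioned on an observed n.
#'
#' @param spec a `bp_model`.
#' @param w a `bp_window`.
#' @param seed optional integer seed.
#' @return a `bp_pattern`.
#' @export
simulate_model <- function(spec, w, seed = NULL) {
  stopifnot(inherits(spec, "bp_model"), inherits(w, "bp_window"))
  if (!is.null(seed)) set.seed(seed)
  switch(spec$model,
         hom_poisson = sim_hom(spec, w),
         inhom_poisson = sim_inhom(spec, w),
         thomas = sim_thomas(spec, w),
         pair_process = sim_pairs(spec, w),
         stop("unknown model"))
}

sim_hom <- function(spec, w) {
  n <- stats::rpois(1, spec$lambda * window_area(w))
  xy <- uniform_points(w, n)
  point_pattern(xy, window = w)
}

sim_inhom <- function(spec, w) {
  b <- spec$beta
  # log-linear intensity attains its maximum at a bounding-box corner
  corners <- expand.grid(x = w$xrange, y = w$yrange)
  lmax <- max(exp(b[1] + b[2] * corners$x + b[3] * corners$y))
  n0 <- stats::rpois(1, lmax * diff(w$xrange) * diff(w$yrange))
  px <- stats::runif(n0, w$xrange[1], w$xrange[2])
  py <- stats::runif(n0, w$yrange[1], w$yrange[2])
  lam <- exp(b[1] + b[2] * px + b[3] * py)
  keep <- stats::runif(n0) < lam / lmax & contains(w, px, py)
  point_pattern(px[keep], py[keep], window = w)
}

# parents on the dilated bounding box; valid because a Poisson parent process
# restricted to any superset of the dilated window is again Poisson
parent_points <- function(w, kappa, buffer) {
  xr <- w$xrange + c(-buffer, buffer)
  yr <- w$yrange + c(-buffer, buffer)
  np <- stats::rpois(1, kappa * diff(xr) * diff(yr))
  cbind(stats::runif(np, xr[1], xr[2]), stats::runif(np, yr[1], yr[2]))
}

sim_thomas <- function(spec, w, buffer = 4 * spec$sigma) {
  par <- parent_points(w, spec$kappa, buffer)
  counts <- stats::rpois(nrow(par), spec$mu)
  tot <- sum(counts)
  if (tot == 0) return(point_pattern(numeric(0), numeric(0), window = w))
  cx <- rep(par[, 1], counts) + stats::rnorm(tot, 0, spec$sigma)
  cy <- rep(par[, 2], counts) + stats::rnorm(tot, 0, spec$sigma)
  keep <- contains(w, cx, cy)
  point_pattern(cx[keep], cy[keep], window = w)
}

sim_pairs <- function(spec, w, buffer = spec$r_c) {
  par <- parent_points(w, spec$kappa, buffer)
  np <- nrow(par)
  if (np == 0) return(point_pattern(numeric(0), numeric(0), window = w))
  # two independent uniform points in the disc of radius r_c per parent
  rr <- spec$r_c * sqrt(stats::runif(2 * np))
  th <- stats::runif(2 * np, 0, 2 * pi)
  px <- rep(par[, 1], each = 2) + rr * cos(th)
  py <- rep(par[, 2], each = 2) + rr * sin(th)
  # delete one of the two (chosen at random) with probability 1 - P
  drop_pair <- stats::runif(np) > spec$p_ret
  which_drop <- sample(c(1L, 2L), np, replace = TRUE)
  del <- rep(FALSE, 2 * np)
  del[2 * (which(drop_pair) - 1) + which_drop[drop_pair]] <- TRUE
  keep <- !del & contains(w, px, py)
  point_pattern(px[keep], py[keep], window = w)
}

#' Theoretical K-function of a Thomas process
#'
#' `K(r) = pi r^2 + (1/kappa) (1 - exp(-r^2 / (4 sigma^2)))`.
#' @param spec a Thomas `bp_model`.
#' @param r distance grid.
#' @export
thomas_theoretical_k <- function(spec, r) {
  stopifnot(inherits(spec, "bp_model"), spec$model == "thomas")
  new_summary("K", r, pi * r^2 + (1 - exp(-r^2 / (4 * spec$sigma^2))) / spec$kappa,
              pi * r^2)
}

new_fit <- function(spec, objective, converged, n_evaluations = NA_integer_,
                    seed = NULL, extra = list()) {
  structure(c(list(spec = spec, objective = objective, converged = converged,
                   n_evaluations = n_evaluations, seed = seed), extra),
            class = "bp_fit")
}

#' @export
print.bp_fit <- function(x, ...) {
  cat("fitted ", sep = "")
  print(x$spec)
  cat(sprintf("objective %.6g, converged: %s\n", x$objective, x$converged))
  invisible(x)
}

#' Fit a homogeneous Poisson model
#'
#' The single parameter is the mean intensity itself.
#' @param p a `bp_pattern`.
#' @export
fit_hom_poisson <- function(p) {
  lam <- mean_intensity(p)
  new_fit(hom_poisson(lam), objective = NA_real_, converged = TRUE)
}

#' Fit a log-linear inhomogeneous Poisson model
#'
#' Maximum likelihood with intensity `exp(b0 + b1 x + b2 y)` via the
#' Berman-Turner quadrature device: data points plus a regular dummy grid,
#' with counting weights from the per-tile observable area, turn the point
#' process likelihood into a weighted Poisson regression.
#'
#' @param p a `bp_pattern` with at least 3 points.
#' @param ndummy dummy grid resolution per axis.
#' @return a `bp_fit` carrying `beta`, standard errors `se`, and the
#'   quadrature integral of the fitted intensity (`= n` up to quadrature
#'   error).
#' @export
fit_inhom_poisson <- function(p, ndummy = 32) {
  stopifnot(inherits(p, "bp_pattern"))
  if (p$n < 3) stop("need at least 3 points")
  w <- p$window
  dxs <- seq(w$xrange[1], w$xrange[2], length.out = ndummy + 1)
  dys <- seq(w$yrange[1], w$yrange[2], length.out = ndummy + 1)
  cx <- (dxs[-1] + dxs[-length(dxs)]) / 2
  cy <- (dys[-1] + dys[-length(dys)]) / 2
  dum <- expand.grid(x = cx, y = cy)
  dum <- dum[contains(w, dum$x, dum$y), ]
  # observable area of each tile from the cached window mask
  msk <- window_mask(w, 256)
  tile_of <- function(x, y) {
    ix <- pmin(pmax(findInterval(x, dxs, all.inside = TRUE), 1), ndummy)
    iy <- pmin(pmax(findInterval(y, dys, all.inside = TRUE), 1), ndummy)
    (iy - 1) * ndummy + ix
  }
  mx <- rep(msk$gx, each = length(msk$gy))
  my <- rep(msk$gy, times = length(msk$gx))
  tin <- tile_of(mx, my)
  px_area <- msk$dx * msk$dy
  tile_area <- numeric(ndummy^2)
  tab <- tapply(as.numeric(msk$m), tin, sum)
  tile_area[as.integer(names(tab))] <- tab * px_area
  qx <- c(p$x, dum$x); qy <- c(p$y, dum$y)
  z <- c(rep(1, p$n), rep(0, nrow(dum)))
  tq <- tile_of(qx, qy)
  cnt <- table(tq)
  wq <- tile_area[tq] / as.numeric(cnt[as.character(tq)])
  ok <- wq > 0
  fit <- suppressWarnings(
    stats::glm((z / wq)[ok] ~ qx[ok] + qy[ok], family = stats::poisson(),
               weights = wq[ok]))
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  integ <- sum(wq[ok] * exp(beta[1] + beta[2] * qx[ok] + beta[3] * qy[ok]))
  new_fit(inhom_poisson(beta), objective = -as.numeric(stats::logLik(fit)),
          converged = fit$converged,
          extra = list(se = se, intensity_integral = integ))
}

# integrated (K^q - Ktheo^q)^2 by the trapezoid rule
contrast_integral <- function(r, kobs, kmod, q = 0.25) {
  f <- (pmax(kobs, 0)^q - pmax(kmod, 0)^q)^2
  sum((f[-1] + f[-length(f)]) / 2 * diff(r))
}

#' Fit a Thomas cluster process by minimum contrast
#'
#' Minimises the integrated squared difference between the fourth roots of
#' the empirical and theoretical K-functions over `[0, rmax]` (Nelder-Mead on
#' the log scale). The offspring mean is then fixed by the intensity
#' identity `mu = lambda / kappa`.
#'
#' @param p a `bp_pattern` with at least 10 points.
#' @param rmax,nr contrast integration range and grid size.
#' @param dimyx raster resolution for polygonal set covariance.
#' @return a `bp_fit` with a Thomas `bp_model` spec.
#' @export
fit_thomas_mincontrast <- function(p, rmax = NULL, nr = 257, dimyx = 256) {
  stopifnot(inherits(p, "bp_pattern"))
  if (p$n < 10) stop("minimum-contrast fitting needs at least 10 points")
  w <- p$window
  if (is.null(rmax)) rmax <- default_rmax(w)
  r <- seq(0, rmax, length.out = nr)
  kobs <- k_translation(p, r = r, dimyx = dimyx)$est
  lam <- mean_intensity(p)
  obj <- function(par) {
    kappa <- exp(par[1]); sigma <- exp(par[2])
    kmod <- pi * r^2 + (1 - exp(-r^2 / (4 * sigma^2))) / kappa
    contrast_integral(r, kobs, kmod)
  }
  start <- c(log(lam / 2), log(0.1 * rmax))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
  kappa <- exp(opt$par[1]); sigma <- exp(opt$par[2])
  new_fit(thomas_process(kappa, sigma, mu = lam / kappa),
          objective = opt$value, converged = opt$convergence == 0,
          n_evaluations = opt$counts[1])
}

#' Fit the pair process by simulation-based minimum contrast
#'
#' The pair process has no known closed-form K, so the model curve at each
#' candidate parameter value is estimated from `m_sims` simulated patterns.
#' The contrast matches the *fourth root* of the observed K against the
#' pointwise mean of the fourth roots of the simulated Ks: since observed
#' and simulated curves are then the same functional of the same estimator,
#' they are exchangeable when the candidate equals the truth and the
#' matching is centred (taking the fourth root of the averaged K instead
#' biases the fit towards weaker clustering, because the transform is
#' concave and the observed curve is a single noisy draw). Common random
#' numbers (a fixed pool of simulation seeds reused at every objective
#' evaluation) make the objective deterministic so Nelder-Mead does not
#' chase Monte-Carlo noise. The parent intensity is constrained by the
#' intensity identity `kappa = lambda / (1 + P)`, leaving two free
#' parameters, optimised as `(log r_c, logit P)`. Because the objective is
#' nearly flat in P at realistic sample sizes (the K excess scales only as
#' `2P/(1+P)`) and piecewise-steppy in the parameters (simulated counts are
#' discrete), Nelder-Mead started from a single point stalls near its
#' start; the optimiser is therefore started from the best node of a
#' deterministic coarse grid over `(r_c, P)` and Nelder-Mead only polishes
#' that choice.
#'
#' @param p a `bp_pattern` with at least 10 points.
#' @param m_sims simulated patterns per objective evaluation.
#' @param seed integer seed for the common-random-number pool.
#' @param rmax,nr contrast integration range and grid size.
#' @param dimyx raster resolution for polygonal set covariance.
#' @param maxit Nelder-Mead evaluation budget.
#' @return a `bp_fit` with a `pair_process` spec; `boundary` flags an
#'   optimum pinned at P near 0 or 1, and `no_signal` flags an objective
#'   that a degenerate no-pairing model (P ~ 0) fits almost as well, i.e. a
#'   pattern with no detectable pair structure.
#' @export
fit_pair_mincontrast <- function(p, m_sims = 100, seed = NULL,
                                 rmax = NULL, nr = 129, dimyx = 256,
                                 maxit = 100) {
  stopifnot(inherits(p, "bp_pattern"))
  if (p$n < 10) stop("minimum-contrast fitting needs at least 10 points")
  w <- p$window
  if (is.null(rmax)) rmax <- default_rmax(w)
  r <- seq(0, rmax, length.out = nr)
  kobs4 <- pmax(k_translation(p, r = r, dimyx = dimyx)$est, 0)^0.25
  lam <- mean_intensity(p)
  if (!is.null(seed)) set.seed(seed)
  seed_pool <- sample.int(2^31 - 2, m_sims)
  neval <- 0L
  obj <- function(par) {
    r_c <- exp(par[1]); pret <- stats::plogis(par[2])
    spec <- pair_process(lam / (1 + pret), r_c, pret)
    acc <- numeric(length(r))
    for (s in seed_pool) {
      sim <- simulate_model(spec, w, seed = s)
      tries <- 0
      while (sim$n < 2 && tries < 20) {
        sim <- simulate_model(spec, w, seed = s + 7919 * (tries <- tries + 1))
      }
      acc <- acc + pmax(k_translation(sim, r = r, dimyx = dimyx)$est, 0)^0.25
    }
    neval <<- neval + 1L
    f <- (kobs4 - acc / m_sims)^2
    sum((f[-1] + f[-length(f)]) / 2 * diff(r))
  }
  # deterministic grid pre-search, then Nelder-Mead polish
  grid <- expand.grid(lrc = log(rmax * c(0.05, 0.075, 0.1, 0.15, 0.2, 0.3)),
                      lp = stats::qlogis(seq(0.1, 0.9, by = 0.1)))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  r_c <- exp(opt$par[1]); pret <- stats::plogis(opt$par[2])
  # no-signal diagnostic: compare the optimum against the degenerate
  # no-pairing model (P ~ 0, i.e. plain Poisson at lambda) on a *fresh*
  # seed pool. Re-evaluating on held-out randomness removes the selection
  # bias of having minimised over the original pool, so on CSR input the
  # two agree and the fit is flagged as carrying no pair signal.
  seed_pool <- seed_pool + 1L
  obj_opt_fresh <- obj(opt$par)
  obj_null_fresh <- obj(c(opt$par[1], stats::qlogis(1e-3)))
  new_fit(pair_process(lam / (1 + pret), r_c, pret),
          objective = opt$value,
          converged = opt$convergence == 0,
          n_evaluations = neval, seed = seed,
          extra = list(boundary = pret < 0.01 || pret > 0.99,
                       objective_null = obj_null_fresh,
                       no_signal = obj_opt_fresh > 0.5 * obj_null_fresh))
}
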