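#' Monte-Carlo inference for fitted point-process models
#'
#' Both tools simulate `n_sim` patterns from a fitted (or specified) model in
#' the observed pattern's window and compare summary functions. Envelopes
#' are the pointwise minimum/maximum band of the simulated curves; the
#' Diggle-Cressie-Loosmore-Ford (DCLF) test ranks the integrated squared
#' deviation of the observed curve among the simulated ones.
#'
#' @name inference
NULL

model_spec_of <- function(model) {
  if (inherits(model, "bp_fit")) model$spec
  else if (inherits(model, "bp_model")) model
  else stop("model must be a bp_model or bp_fit")
}

summary_curve <- function(p, statistic, r, dimyx, bandwidth = NULL) {
  switch(statistic,
         K = k_translation(p, r = r, dimyx = dimyx)$est,
         L = l_translation(p, r = r, dimyx = dimyx)$est,
         g = pair_correlation(p, r = r, dimyx = dimyx,
                              bandwidth = bandwidth)$est,
         stop("statistic must be one of K, L, g"))
}

simulate_valid <- function(spec, w, seed, retry_cap = 50) {
  sim <- simulate_model(spec, w, seed = seed)
  tries <- 0
  while (sim$n < 2 && tries < retry_cap) {
    tries <- tries + 1
    sim <- simulate_model(spec, w, seed = seed + 7919 * tries)
  }
  if (sim$n < 2) stop("model keeps producing patterns with < 2 points")
  if (tries > 0)
    message("resampled ", tries, " degenerate simulation(s)")
  sim
}

#' Pointwise Monte-Carlo simulation envelope
#'
#' @param p the observed `bp_pattern`.
#' @param model a `bp_model` or `bp_fit` to simulate from.
#' @param statistic one of "L" (default) or "g" (or "K").
#' @param n_sim number of simulations (99 gives the conventional band).
#' @param seed integer seed.
#' @param r optional distance grid.
#' @param dimyx raster resolution for polygonal set covariance.
#' @param bandwidth pcf bandwidth when `statistic = "g"` (fixed across
#'   simulations so curves are comparable).
#' @return a `bp_envelope` with fields `r`, `obs`, `lo`, `mean`, `hi`.
#' @export
mc_envelope <- function(p, model, statistic = c("L", "g", "K"), n_sim = 99,
                        seed = NULL, r = NULL, dimyx = 256, bandwidth = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(p, "bp_pattern"), n_sim >= 1)
  spec <- model_spec_of(model)
  w <- p$window
  if (is.null(r)) r <- default_rgrid(w)
  if (statistic == "g" && is.null(bandwidth))
    bandwidth <- 0.15 / sqrt(mean_intensity(p))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_sim)
  obs <- summary_curve(p, statistic, r, dimyx, bandwidth)
  sims <- matrix(NA_real_, n_sim, length(r))
  for (i in seq_len(n_sim)) {
    sims[i, ] <- summary_curve(simulate_valid(spec, w, seeds[i]),
                               statistic, r, dimyx, bandwidth)
  }
  structure(list(r = r, obs = obs,
                 lo = apply(sims, 2, min),
                 mean = colMeans(sims),
                 hi = apply(sims, 2, max),
                 n_sim = n_sim, statistic = statistic,
                 model = spec$model, seed = seed),
            class = "bp_envelope")
}

#' @export
print.bp_envelope <- function(x, ...) {
  out <- sum(x$obs < x$lo | x$obs > x$hi, na.rm = TRUE)
  cat(sprintf("%s envelope (%d sims, model %s): observed outside the band at %d of %d r values\n",
              x$statistic, x$n_sim, x$model, out, length(x$r)))
  invisible(x)
}

#' Plot a Monte-Carlo envelope
#' @param x a `bp_envelope`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bp_envelope <- function(x, ...) {
  graphics::plot(x$r, x$obs, type = "n",
                 ylim = range(c(x$obs, x$lo, x$hi), finite = TRUE),
                 xlab = "r (m)", ylab = x$statistic, ...)
  graphics::polygon(c(x$r, rev(x$r)), c(x$lo, rev(x$hi)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::lines(x$r, x$mean, lty = 2)
  graphics::lines(x$r, x$obs, lwd = 2)
  invisible(x)
}

#' Diggle-Cressie-Loosmore-Ford goodness-of-fit test
#'
#' The deviation measure for each curve i (the observed curve and each
#' simulated one, treated symmetrically) is
#' `u_i = sum_k (H_i(r_k) - Hbar_(-i)(r_k))^2 dr`, where `Hbar_(-i)` is the
#' mean of all the other curves. The p-value is
#' `(1 + #{u_sim >= u_obs}) / (n_sim + 1)`; ties count towards rejection
#' (conservative), and the smallest attainable p with 99 simulations is
#' 0.01.
#'
#' @inheritParams mc_envelope
#' @param statistic one of "L" (default, variance-stabilised), "K", "g".
#' @param r_range integration range `c(rmin, rmax)`; default the whole grid.
#' @return a `bp_gof` with `u_obs`, `u_sim`, `p_value`.
#' @export
dclf_test <- function(p, model, statistic = c("L", "K", "g"), n_sim = 99,
                      seed = NULL, r = NULL, r_range = NULL, dimyx = 256,
                      bandwidth = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(p, "bp_pattern"), n_sim >= 1)
  spec <- model_spec_of(model)
  w <- p$window
  if (is.null(r)) r <- default_rgrid(w)
  if (statistic == "g" && is.null(bandwidth))
    bandwidth <- 0.15 / sqrt(mean_intensity(p))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_sim)
  curves <- matrix(NA_real_, n_sim + 1, length(r))
  curves[1, ] <- summary_curve(p, statistic, r, dimyx, bandwidth)
  for (i in seq_len(n_sim)) {
    curves[i + 1, ] <- summary_curve(simulate_valid(spec, w, seeds[i]),
                                     statistic, r, dimyx, bandwidth)
  }
  keep <- rep(TRUE, length(r))
  if (!is.null(r_range)) keep <- r >= r_range[1] & r <= r_range[2]
  dr <- mean(diff(r))
  cm <- curves[, keep, drop = FALSE]
  tot <- colSums(cm)
  m <- nrow(cm)
  u <- vapply(seq_len(m), function(i) {
    hbar <- (tot - cm[i, ]) / (m - 1)
    sum((cm[i, ] - hbar)^2) * dr
  }, 0)
  p_value <- (1 + sum(u[-1] >= u[1])) / (n_sim + 1)
  structure(list(u_obs = u[1], u_sim = u[-1], p_value = p_value,
                 n_sim = n_sim, statistic = statistic,
                 r_range = range(r[keep]), model = spec$model, seed = seed),
            class = "bp_gof")
}

#' @export
print.bp_gof <- function(x, ...) {
  cat(sprintf("DCLF test (%s, %d sims, model %s): u = %.4g, p = %.3g\n",
              x$statistic, x$n_sim, x$model, x$u_obs, x$p_value))
  invisible(x)
}
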