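#' Circular statistics for shell orientations
#'
#' Orientations are directions in degrees, counterclockwise from the +x
#' axis, taken in the adoral direction of the shell. The mean resultant
#' length Rbar measures concentration (1 = all aligned, 0 = balanced); the
#' angular standard deviation used here is the circular standard deviation
#' `v = sqrt(-2 ln Rbar)` (in degrees), which diverges as the sample
#' becomes uniform.
#'
#' @param angles_deg numeric vector of directions in degrees.
#' @return a `bp_circular` with `n`, `rbar`, `theta_deg`, `v_deg`
#'   (`NA` with `undefined = TRUE` when `rbar == 0`).
#' @export
circular_summary <- function(angles_deg) {
  if (!length(angles_deg)) stop("no angles supplied")
  a <- angles_deg * pi / 180
  C <- mean(cos(a)); S <- mean(sin(a))
  rbar <- sqrt(C^2 + S^2)
  if (rbar < .Machine$double.eps) {
    return(structure(list(n = length(a), rbar = 0, theta_deg = NA_real_,
                          v_deg = NA_real_, undefined = TRUE),
                     class = "bp_circular"))
  }
  theta <- atan2(S, C) %% (2 * pi)
  structure(list(n = length(a), rbar = rbar,
                 theta_deg = theta * 180 / pi,
                 v_deg = angular_sd_deg(rbar), undefined = FALSE),
            class = "bp_circular")
}

#' Angular standard deviation implied by a mean resultant length
#'
#' `v = (180 / pi) * sqrt(-2 ln Rbar)` degrees.
#' @param rbar mean resultant length in (0, 1].
#' @export
angular_sd_deg <- function(rbar) {
  stopifnot(all(rbar > 0), all(rbar <= 1))
  sqrt(-2 * log(rbar)) * 180 / pi
}

#' @export
print.bp_circular <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("circular summary: n = %d, Rbar = 0 (direction undefined)\n", x$n))
  } else {
    cat(sprintf("circular summary: n = %d, Rbar = %.2f, theta = %.0f deg, v = %.0f deg\n",
                x$n, x$rbar, x$theta_deg, x$v_deg))
  }
  invisible(x)
}

#' Kuiper's test of circular uniformity
#'
#' Rotation-invariant analogue of the Kolmogorov-Smirnov test:
#' `V = D+ + D-` against the uniform circular distribution, with the
#' finite-sample modification `V* = V (sqrt(n) + 0.155 + 0.24 / sqrt(n))`
#' and the asymptotic tail series
#' `p = sum_m 2 (4 m^2 V*^2 - 1) exp(-2 m^2 V*^2)`.
#'
#' @param angles_deg directions in degrees; at least 5.
#' @return a `bp_kuiper` with `V`, `V_star`, `p_value`, `n`.
#' @export
kuiper_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 5) stop("Kuiper's test needs at least 5 angles")
  u <- sort((angles_deg %% 360) / 360)
  i <- seq_len(n)
  dplus <- max(i / n - u)
  dminus <- max(u - (i - 1) / n)
  V <- dplus + dminus
  vs <- V * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
  p <- kuiper_tail(vs)
  structure(list(V = V, V_star = vs, p_value = min(max(p, .Machine$double.xmin), 1),
                 n = n), class = "bp_kuiper")
}

kuiper_tail <- function(vs, tol = 1e-10, mmax = 100) {
  p <- 0
  for (m in seq_len(mmax)) {
    term <- 2 * (4 * m^2 * vs^2 - 1) * exp(-2 * m^2 * vs^2)
    p <- p + term
    if (abs(term) < tol) break
  }
  p
}

#' @export
print.bp_kuiper <- function(x, ...) {
  cat(sprintf("Kuiper test: n = %d, V = %.4f, V* = %.4f, p = %.3g\n",
              x$n, x$V, x$V_star, x$p_value))
  invisible(x)
}

#' Rose diagram of orientations
#'
#' Counts per angular bin drawn as wedges; a quick visual check of
#' current alignment.
#' @param angles_deg directions in degrees.
#' @param bin bin width in degrees (default 10).
#' @param ... passed to [graphics::plot()].
#' @export
rose_diagram <- function(angles_deg, bin = 10, ...) {
  breaks <- seq(0, 360, by = bin)
  cnt <- graphics::hist(angles_deg %% 360, breaks = breaks, plot = FALSE)$counts
  rmax <- max(cnt, 1)
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  for (k in seq_along(cnt)) {
    if (cnt[k] == 0) next
    th <- seq(breaks[k], breaks[k + 1], length.out = 10) * pi / 180
    graphics::polygon(c(0, cnt[k] * cos(th)), c(0, cnt[k] * sin(th)),
                      col = grDevices::grey(0.7))
  }
  invisible(cnt)
}
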