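#' Marked planar point patterns
#'
#' A point pattern is a set of fossil positions (metres) inside an
#' observation window, optionally carrying per-point marks: taxon,
#' orientation of the shell in degrees (counterclockwise from +x, adoral
#' direction), and conch length/width in millimetres.
#'
#' @param x,y coordinate vectors in metres (or `x` a two-column matrix).
#' @param window a [win_rect()] / [win_poly()] window.
#' @param marks optional data.frame with any of the columns `taxon`,
#'   `angle_deg`, `length_mm`, `width_mm`; one row per point.
#' @return an object of class `bp_pattern`.
#' @export
point_pattern <- function(x, y = NULL, window, marks = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(inherits(window, "bp_window"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- contains(window, x, y)
  if (!all(ok))
    stop("point(s) outside the window: rows ", paste(which(!ok), collapse = ", "))
  if (anyDuplicated(cbind(x, y)))
    warning("duplicate coordinates present (coincident outline centres)")
  if (!is.null(marks)) {
    marks <- as.data.frame(marks)
    stopifnot(nrow(marks) == length(x))
    if (!is.null(marks$angle_deg)) {
      bad <- !is.na(marks$angle_deg) & (marks$angle_deg < 0 | marks$angle_deg >= 360)
      marks$angle_deg[!is.na(marks$angle_deg)] <-
        marks$angle_deg[!is.na(marks$angle_deg)] %% 360
      if (any(bad)) marks$angle_deg <- marks$angle_deg %% 360
    }
    for (col in c("length_mm", "width_mm"))
      if (!is.null(marks[[col]]) && any(!is.na(marks[[col]]) & marks[[col]] <= 0))
        stop(col, " marks must be positive")
  }
  structure(list(x = x, y = y, window = window, marks = marks,
                 n = length(x)),
            class = "bp_pattern")
}

#' @export
print.bp_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points, mean intensity %.3g / m^2\n",
              x$n, mean_intensity(x)))
  print(x$window)
  if (!is.null(x$marks))
    cat("marks:", paste(names(x$marks), collapse = ", "), "\n")
  invisible(x)
}

#' Mean intensity (points per square metre)
#'
#' The average number of specimens per unit of observable area,
#' `n / area(window)`.
#' @param p a `bp_pattern`.
#' @export
mean_intensity <- function(p) {
  stopifnot(inherits(p, "bp_pattern"))
  A <- window_area(p$window)
  if (A <= 0) stop("window has zero area")
  p$n / A
}

#' Subset a pattern by taxon
#' @param p a `bp_pattern`.
#' @param taxon taxon label to keep.
#' @export
subset_taxon <- function(p, taxon) {
  stopifnot(inherits(p, "bp_pattern"))
  if (is.null(p$marks$taxon)) stop("pattern has no taxon marks")
  keep <- which(p$marks$taxon == taxon)
  point_pattern(p$x[keep], p$y[keep], p$window,
                marks = p$marks[keep, , drop = FALSE])
}

#' Kernel-smoothed intensity map
#'
#' Isotropic Gaussian kernel estimate of the intensity surface on a grid over
#' the window's bounding box. Each cell's raw density is divided by the
#' kernel mass falling inside the window (uniform edge correction), so the
#' map integrates to approximately `n` over the window mask.
#'
#' @param p a `bp_pattern`.
#' @param bandwidth Gaussian sigma in metres; default one tenth of the
#'   shorter bounding-box side.
#' @param cell grid cell size in metres; default `bandwidth / 2`.
#' @return an object of class `bp_intensity_map` with fields `z` (matrix,
#'   rows = y), `gx`, `gy`, `mask`, `cell`, `bandwidth`. Values are
#'   points per square metre; `NA` outside the window.
#' @export
kernel_intensity_map <- function(p, bandwidth = NULL, cell = NULL) {
  stopifnot(inherits(p, "bp_pattern"))
  w <- p$window
  side <- min(diff(w$xrange), diff(w$yrange))
  if (is.null(bandwidth)) bandwidth <- 0.1 * side
  if (is.null(cell)) cell <- bandwidth / 2
  stopifnot(bandwidth > 0, cell > 0)
  if (cell > min(diff(w$xrange), diff(w$yrange)))
    stop("cell size exceeds the window extent")
  gx <- seq(w$xrange[1] + cell / 2, w$xrange[2], by = cell)
  gy <- seq(w$yrange[1] + cell / 2, w$yrange[2], by = cell)
  mask <- outer(gy, gx, function(yy, xx) contains(w, xx, yy))
  z <- matrix(0, length(gy), length(gx))
  if (p$n > 0) {
    for (i in seq_len(p$n)) {
      kx <- stats::dnorm(gx, p$x[i], bandwidth)
      ky <- stats::dnorm(gy, p$y[i], bandwidth)
      z <- z + ky %*% t(kx)
    }
  }
  # edge correction: kernel mass inside the window per grid cell
  if (p$n > 0) {
    inx <- outer(gx, gx, function(a, b) stats::dnorm(a - b, 0, bandwidth)) * cell
    iny <- outer(gy, gy, function(a, b) stats::dnorm(a - b, 0, bandwidth)) * cell
    mnum <- mask * 1
    corr <- iny %*% mnum %*% t(inx)    # mass of kernel centred at cell inside W
    corr[corr < 1e-8] <- 1
    z <- z / corr
  }
  z[!mask] <- NA_real_
  structure(list(z = z, gx = gx, gy = gy, mask = mask, cell = cell,
                 bandwidth = bandwidth, n = p$n),
            class = "bp_intensity_map")
}

#' Integral of an intensity map over the window mask
#' @param m a `bp_intensity_map`.
#' @export
intensity_map_mass <- function(m) {
  stopifnot(inherits(m, "bp_intensity_map"))
  sum(m$z[m$mask], na.rm = TRUE) * m$cell^2
}

#' Conch size summary
#'
#' Arithmetic mean and median of the length and width marks for one taxon.
#' @param p a `bp_pattern` with size marks.
#' @param taxon taxon label; `NULL` pools all points.
#' @return list with `mean_length_mm`, `median_length_mm`, `mean_width_mm`,
#'   `median_width_mm`, `n_with_size`, and `empty` flag.
#' @export
size_summary <- function(p, taxon = NULL) {
  stopifnot(inherits(p, "bp_pattern"))
  m <- p$marks
  keep <- rep(TRUE, p$n)
  if (!is.null(taxon)) {
    if (is.null(m$taxon)) stop("pattern has no taxon marks")
    keep <- !is.na(m$taxon) & m$taxon == taxon
  }
  len <- m$length_mm[keep]; wid <- m$width_mm[keep]
  has <- !is.na(len) & !is.na(wid)
  if (!length(has) || !any(has))
    return(structure(list(empty = TRUE, n_with_size = 0L), class = "bp_size_summary"))
  structure(list(empty = FALSE,
                 mean_length_mm = mean(len[has]),
                 median_length_mm = stats::median(len[has]),
                 mean_width_mm = mean(wid[has]),
                 median_width_mm = stats::median(wid[has]),
                 n_with_size = sum(has)),
            class = "bp_size_summary")
}

#' Read / write the pattern CSV interchange format
#'
#' Columns: `id, x_m, y_m, taxon, angle_deg, length_mm, width_mm`; blank mark
#' cells are allowed.
#' @param path CSV file path.
#' @param window a `bp_window` the points must lie in.
#' @rdname pattern_csv
#' @export
read_pattern_csv <- function(path, window) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_m", "y_m")
  if (!all(need %in% names(d)))
    stop("pattern CSV must have columns id, x_m, y_m")
  bad <- which(!is.finite(d$x_m) | !is.finite(d$y_m))
  if (length(bad))
    stop("malformed coordinate in CSV row(s): ", paste(bad, collapse = ", "))
  out <- which(!contains(window, d$x_m, d$y_m))
  if (length(out))
    stop("point(s) outside the window (or inside a gap) at CSV row(s): ",
         paste(out, collapse = ", "))
  known <- c("Oncocerida", "Ammonoidea", "Orthocerida", "other")
  marks <- data.frame(taxon = if (is.null(d$taxon)) rep(NA_character_, nrow(d)) else d$taxon,
                      angle_deg = if (is.null(d$angle_deg)) NA_real_ else d$angle_deg,
                      length_mm = if (is.null(d$length_mm)) NA_real_ else d$length_mm,
                      width_mm = if (is.null(d$width_mm)) NA_real_ else d$width_mm,
                      stringsAsFactors = FALSE)
  unk <- !is.na(marks$taxon) & !(marks$taxon %in% known)
  if (any(unk)) {
    warning("unknown taxon label(s) kept as 'other': ",
            paste(unique(marks$taxon[unk]), collapse = ", "))
    marks$taxon[unk] <- "other"
  }
  point_pattern(d$x_m, d$y_m, window, marks = marks)
}

#' @param p a `bp_pattern`.
#' @rdname pattern_csv
#' @export
write_pattern_csv <- function(p, path) {
  m <- p$marks
  d <- data.frame(id = seq_len(p$n), x_m = p$x, y_m = p$y,
                  taxon = if (is.null(m$taxon)) NA else m$taxon,
                  angle_deg = if (is.null(m$angle_deg)) NA else m$angle_deg,
                  length_mm = if (is.null(m$length_mm)) NA else m$length_mm,
                  width_mm = if (is.null(m$width_mm)) NA else m$width_mm)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}
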