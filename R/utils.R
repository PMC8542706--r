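#' @keywords internal
"_PACKAGE"

## Small numeric helpers shared across modules. Lengths are mm throughout.

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' @param a,b semi-axes in mm.
#' @return Perimeter in mm. Accurate to well below mesh discretisation error
#'   for the mild eccentricities of aortic annuli.
#' @keywords internal
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Radius of a centred ellipse at polar angle theta
#' @keywords internal
ellipse_radius <- function(theta, a, b) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

#' Shoelace area of a simple polygon
#' @param xy two-column matrix of vertices in order.
#' @keywords internal
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Perimeter of a closed polygon
#' @keywords internal
polygon_perimeter <- function(xy) {
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
}

#' Maximum pairwise vertex distance (polygon diameter)
#' @keywords internal
polygon_dmax <- function(xy) {
  max(stats::dist(xy))
}

#' Minimum width of the convex hull (rotating-calipers equivalent)
#'
#' For every hull edge, the width is the maximum distance of hull vertices
#' from the edge's supporting line; the minimum over edges is the polygon's
#' minimum width. O(h^2), ample for cross-section polygons.
#' @keywords internal
polygon_dmin <- function(xy) {
  h <- grDevices::chull(xy)
  hv <- xy[h, , drop = FALSE]
  n <- nrow(hv)
  if (n < 3) stop("degenerate polygon: convex hull has fewer than 3 vertices")
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- hv[j, ] - hv[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    d <- (hv[, 1] - hv[i, 1]) * nrm[1] + (hv[, 2] - hv[i, 2]) * nrm[2]
    max(d) - min(d)
  }, numeric(1))
  min(widths)
}

#' Truncated-normal sampling by rejection
#'
#' Draws from N(mean, sd) truncated to [lower, upper]. Rejection is adequate
#' for the mild truncations used by the cohort generator; a hard cap on
#' attempts guards against infeasible bounds.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower >= upper) stop("infeasible truncation bounds: lower >= upper")
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate distribution outside bounds")
    return(rep(mean, n))
  }
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    tries <- tries + 1L
    if (tries > 1000L) stop("truncation bounds reject essentially all mass")
  }
  out[seq_len(n)]
}

#' Wrap angles into [0, 2*pi)
#' @keywords internal
wrap_angle <- function(theta) {
  theta %% (2 * pi)
}

#' Smallest absolute angular difference between two angles
#' @keywords internal
angle_diff <- function(a, b) {
  d <- abs(wrap_angle(a) - wrap_angle(b))
  pmin(d, 2 * pi - d)
}

#' Linear interpolation of a piecewise profile
#' @param x query points; `xp`, `yp` profile knots (xp strictly increasing).
#' @keywords internal
interp_profile <- function(x, xp, yp) {
  if (any(diff(xp) <= 0)) stop("profile heights must be strictly increasing")
  stats::approx(xp, yp, xout = x, rule = 2)$y
}

#' Stable per-patient seed stream derived from a master seed
#' @keywords internal
derive_seed <- function(master, index, stream = 0L) {
  (as.integer(master) %% 1000000L) * 1000L + as.integer(index) * 7L +
    as.integer(stream) %% 7L
}
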