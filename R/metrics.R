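## Frame deformation metrics: cross-section polygons at the standard device
## levels (ventricular end, nadir, central coaptation, commissures) and the
## predicted-vs-observed comparison statistics (mean difference, R^2).

#' Standard device measurement levels
#'
#' Heights as fractions of the frame height, strictly increasing from the
#' ventricular end. The fractions are configuration (the exact axial
#' definitions are device-specific).
#'
#' @param fractions named numeric vector of height fractions in [0, 1].
#' @return named numeric vector (validated).
#' @export
level_specs <- function(fractions = c(ventricular_end = 0.02, nadir = 0.15,
                                      central_coaptation = 0.45,
                                      commissures = 0.70)) {
  if (any(fractions < 0 | fractions > 1))
    stop("level fractions must lie in [0, 1]")
  if (any(diff(fractions) <= 0))
    stop("level fractions must be strictly increasing from ventricular_end")
  fractions
}

#' Cross-section polygon of a frame at height z
#'
#' Interpolates each sector's node column at `z` (anatomy coordinates) and
#' returns the points ordered by angle about the section centroid.
#'
#' @param frame a `frame_mesh`.
#' @param z section height (mm) within the frame's axial extent.
#' @return two-column matrix (x, y), one ordered vertex per sector.
#' @export
cross_section <- function(frame, z) {
  stopifnot(inherits(frame, "frame_mesh"))
  if (z < min(frame$z) - 1e-9 || z > max(frame$z) + 1e-9)
    stop("z = ", z, " lies outside the frame axial extent [",
         round(min(frame$z), 2), ", ", round(max(frame$z), 2), "]")
  ns <- ncol(frame$radii)
  pts <- matrix(NA_real_, ns, 2)
  for (s in seq_len(ns)) {
    r <- stats::approx(frame$z, frame$radii[, s], xout = z, rule = 2)$y
    th <- frame$angles[1, s]
    pts[s, ] <- c(r * cos(th), r * sin(th))
  }
  ctr <- colMeans(pts)
  pts[order(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])), , drop = FALSE]
}

#' Measure a cross-section polygon
#'
#' `dmax` is the maximum pairwise vertex distance, `dmin` the minimum width
#' of the convex hull (rotating calipers), `perimeter` and `area` those of
#' the polygon itself (shoelace).
#'
#' @param polygon two-column matrix of ordered vertices.
#' @return named numeric vector: `dmax`, `dmin`, `perimeter`, `area`.
#' @export
measure_section <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) stop("degenerate polygon: fewer than 3 vertices")
  if (max(stats::dist(polygon)) < 1e-9) stop("degenerate polygon: zero extent")
  c(dmax = polygon_dmax(polygon),
    dmin = polygon_dmin(polygon),
    perimeter = polygon_perimeter(polygon),
    area = polygon_area(polygon))
}

#' Measure a deployed frame at the standard device levels
#'
#' @param frame a `frame_mesh` (typically from a `deployed_state`).
#' @param levels a [level_specs()] vector.
#' @return data.frame: `level`, `z`, `dmax`, `dmin`, `perimeter`, `area`.
#' @export
measure_frame_levels <- function(frame, levels = level_specs()) {
  zs <- min(frame$z) + levels * (max(frame$z) - min(frame$z))
  rows <- lapply(seq_along(levels), function(i) {
    m <- measure_section(cross_section(frame, zs[i]))
    data.frame(level = names(levels)[i], z = zs[i], dmax = m["dmax"],
               dmin = m["dmin"], perimeter = m["perimeter"],
               area = m["area"], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synthetic post-operative measurements from predicted ones
#'
#' The study compares simulated frames with post-operative imaging; no
#' imaging exists for synthetic anatomies, so observed measurements are
#' emulated as predicted values plus a systematic bias and seeded noise.
#' Explicitly a stand-in for imaging-derived measurements.
#'
#' @param predicted data.frame from [measure_frame_levels()] (or stacked
#'   over patients).
#' @param bias named additive bias for `dmax`, `dmin`, `perimeter`, `area`.
#' @param noise_sd named noise SD on the same scale.
#' @param seed integer seed.
#' @return data.frame of the same shape.
#' @export
perturb_measurements <- function(predicted,
                                 bias = c(dmax = 0.10, dmin = 0.06,
                                          perimeter = 0.34, area = 0.96),
                                 noise_sd = c(dmax = 0.7, dmin = 0.8,
                                              perimeter = 1.6, area = 20),
                                 seed = 1) {
  set.seed(seed)
  out <- predicted
  for (m in c("dmax", "dmin", "perimeter", "area")) {
    out[[m]] <- predicted[[m]] + bias[[m]] +
      stats::rnorm(nrow(predicted), 0, noise_sd[[m]])
  }
  out
}

#' Compare predicted and observed frame measurements
#'
#' For each measurement (dmax, dmin, perimeter, area): the mean and SD of
#' the signed differences observed - predicted, and the coefficient of
#' determination R^2 (squared Pearson correlation of observed vs predicted).
#'
#' @param predicted,observed data.frames with the four measurement columns,
#'   paired row by row (n >= 3).
#' @return data.frame: `measurement`, `mean_diff`, `sd_diff`, `r_squared`.
#' @export
compare_frames <- function(predicted, observed) {
  if (nrow(predicted) != nrow(observed))
    stop("predicted and observed must be paired (equal length)")
  if (nrow(predicted) < 3) stop("need at least 3 paired measurements")
  rows <- lapply(c("dmax", "dmin", "perimeter", "area"), function(m) {
    d <- observed[[m]] - predicted[[m]]
    data.frame(measurement = m, mean_diff = mean(d),
               sd_diff = stats::sd(d),
               r_squared = r_squared(observed[[m]], predicted[[m]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
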