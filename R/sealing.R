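## Skirt sealing analysis: attribute each skirt element to an anatomical
## region by casting a ray along its outward normal, classify apposed /
## malapposed at the 1 mm threshold, and aggregate per-region areas and
## percentages. Areas are summed on the deformed 3D skirt elements; the 2D
## unrolled map is for reporting only.

#' Normal-direction distance from a skirt element to the anatomy
#'
#' Casts a ray from the element centroid along its outward normal and
#' returns the first intersection. When no triangle is hit within
#' `max_ray_length`, falls back to the nearest-point distance and flags the
#' fallback; if even the nearest point is farther than `max_ray_length` the
#' element is `UNRESOLVED`.
#'
#' @param centroid numeric length-3 element centroid (mm).
#' @param normal numeric length-3 outward unit normal.
#' @param anatomy a `surface_mesh` (ideally [prepare_mesh()]-ed).
#' @param max_ray_length search limit (mm).
#' @return list: `distance` (mm), `region`, `material`, `fallback`
#'   (logical).
#' @export
element_distance <- function(centroid, normal, anatomy, max_ray_length = 10) {
  nlen <- sqrt(sum(normal^2))
  if (!is.finite(nlen) || nlen < 1e-9) stop("degenerate element normal")
  normal <- normal / nlen
  hit <- ray_first_hit(anatomy, centroid, normal, tmax = max_ray_length)
  if (hit$hit) {
    return(list(distance = hit$t, region = anatomy$region[hit$triangle],
                material = anatomy$material[hit$triangle], fallback = FALSE))
  }
  np <- mesh_closest_point(anatomy, centroid)
  if (np$distance <= max_ray_length) {
    return(list(distance = np$distance,
                region = anatomy$region[np$triangle],
                material = anatomy$material[np$triangle], fallback = TRUE))
  }
  list(distance = np$distance, region = "UNRESOLVED",
       material = "UNRESOLVED", fallback = TRUE)
}

## Geometry of the deployed skirt elements: centroids, areas (each quad as
## two triangles) and outward normals (cross of the quad diagonals, oriented
## away from the frame axis).
skirt_geometry <- function(frame) {
  nodes <- frame_nodes(frame)
  q <- frame$skirt_elements
  p1 <- nodes[q[, 1], , drop = FALSE]
  p2 <- nodes[q[, 2], , drop = FALSE]
  p3 <- nodes[q[, 3], , drop = FALSE]
  p4 <- nodes[q[, 4], , drop = FALSE]
  centroid <- (p1 + p2 + p3 + p4) / 4
  tri_area <- function(a, b, c3) {
    e1 <- b - a; e2 <- c3 - a
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
  area <- tri_area(p1, p2, p3) + tri_area(p1, p3, p4)
  d1 <- p3 - p1; d2 <- p4 - p2
  nx <- d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2]
  ny <- d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3]
  nz <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  nrm <- cbind(nx, ny, nz)
  len <- sqrt(rowSums(nrm^2))
  ## degenerate quads (fully crimped cells): use the radial direction
  bad <- len < 1e-9
  if (any(bad)) {
    nrm[bad, ] <- cbind(centroid[bad, 1], centroid[bad, 2], 0)
    len[bad] <- sqrt(rowSums(nrm[bad, , drop = FALSE]^2))
  }
  nrm <- nrm / len
  ## orient outward: positive dot with the radial direction
  radial <- cbind(centroid[, 1], centroid[, 2], 0)
  flip <- rowSums(nrm * radial) < 0
  nrm[flip, ] <- -nrm[flip, ]
  list(centroid = centroid, area = area, normal = nrm)
}

#' Per-element sealing records of a deployed state
#'
#' Computes, for every skirt element of the deployed frame, its
#' normal-direction distance to the (deformed) anatomy, the anatomical
#' region it is attributed to, and the apposition flag.
#'
#' @param state a `deployed_state` from [deploy()] / [match_depth()].
#' @param threshold apposition threshold (mm); an element is apposed iff
#'   `distance < threshold` (strict: exactly 1 mm counts as malapposed).
#' @param max_ray_length normal-search limit (mm).
#' @return data.frame with one row per skirt element: `element_id`,
#'   centroid coordinates, `area` (mm^2), `region`, `distance` (mm),
#'   `fallback`, `apposed`.
#' @export
sealing_records <- function(state, threshold = 1, max_ray_length = 10) {
  stopifnot(inherits(state, "deployed_state"))
  anatomy <- prepare_mesh(state$anatomy)
  geo <- skirt_geometry(state$frame)
  n <- nrow(geo$centroid)
  distance <- numeric(n)
  region <- material <- character(n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    ed <- element_distance(geo$centroid[i, ], geo$normal[i, ], anatomy,
                           max_ray_length)
    distance[i] <- ed$distance
    region[i] <- ed$region
    material[i] <- ed$material
    fallback[i] <- ed$fallback
  }
  rec <- data.frame(element_id = seq_len(n),
                    x = geo$centroid[, 1], y = geo$centroid[, 2],
                    z = geo$centroid[, 3],
                    area = geo$area, region = region, material = material,
                    distance = distance, fallback = fallback,
                    stringsAsFactors = FALSE)
  classify_apposition(rec, threshold)
}

#' Classify skirt elements as apposed or malapposed
#'
#' Strict threshold semantics: apposed iff `distance < threshold`, so a
#' distance of exactly 1 mm is malapposed.
#'
#' @param records data.frame with a `distance` column.
#' @param threshold apposition threshold (mm, default 1).
#' @return `records` with an updated logical `apposed` column.
#' @export
classify_apposition <- function(records, threshold = 1) {
  if (threshold < 0) stop("threshold must be >= 0")
  records$apposed <- records$distance < threshold
  records
}

SEAL_REGIONS <- c("LVOT", "INTERLEAFLET_TRIANGLE", "LEAFLET")

#' Summarise sealing records per anatomical region
#'
#' Sums apposed and malapposed element areas on the deformed 3D skirt for
#' the LVOT, interleaflet-triangle and leaflet regions; the ascending aorta
#' is quantified separately and excluded from all totals and percentages.
#' `UNRESOLVED` elements are counted into the nearest resolved region by
#' angular proximity, and their number is reported.
#'
#' @param records output of [sealing_records()].
#' @return object of class `sealing_summary`: `by_region` data.frame
#'   (apposed/malapposed areas in mm^2, per-region malapposition percentage
#'   of the total skirt, apposition contribution percentage), plus
#'   `total_skirt_area`, `malapposition_total_pct`, `apposition_total_pct`,
#'   `ascending_aorta` areas, `n_unresolved`, `unresolved_fraction`.
#' @export
summarize_sealing <- function(records) {
  if (nrow(records) == 0) stop("empty sealing record list")
  if (is.null(records$apposed)) stop("records must be classified first")
  unres <- records$region == "UNRESOLVED"
  if (any(unres)) {
    th_all <- atan2(records$y, records$x)
    ok <- which(!unres)
    if (length(ok) == 0) stop("no resolved skirt elements")
    for (i in which(unres)) {
      j <- ok[which.min(angle_diff(th_all[ok], th_all[i]))]
      records$region[i] <- records$region[j]
    }
  }
  sum_area <- function(reg, app) {
    sum(records$area[records$region == reg & records$apposed == app])
  }
  app <- vapply(SEAL_REGIONS, sum_area, numeric(1), app = TRUE)
  mal <- vapply(SEAL_REGIONS, sum_area, numeric(1), app = FALSE)
  total <- sum(app) + sum(mal)
  if (total <= 0) stop("skirt has no area in the analysed regions")
  by_region <- data.frame(
    region = SEAL_REGIONS,
    apposed_area = app, malapposed_area = mal,
    malapposition_pct = 100 * mal / total,
    apposition_contribution_pct =
      if (sum(app) > 0) 100 * app / sum(app) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    by_region = by_region,
    total_skirt_area = total,
    malapposition_total_pct = 100 * sum(mal) / total,
    apposition_total_pct = 100 * sum(app) / total,
    ascending_aorta = c(
      apposed_area = sum_area("ASCENDING_AORTA", TRUE),
      malapposed_area = sum_area("ASCENDING_AORTA", FALSE)),
    n_unresolved = sum(unres),
    unresolved_fraction = mean(unres)),
    class = "sealing_summary")
}

#' @export
print.sealing_summary <- function(x, ...) {
  cat("sealing_summary: total skirt", round(x$total_skirt_area, 1),
      "mm^2, malapposition", round(x$malapposition_total_pct, 1), "%\n")
  print(transform(x$by_region,
                  apposed_area = round(apposed_area, 1),
                  malapposed_area = round(malapposed_area, 1),
                  malapposition_pct = round(malapposition_pct, 1),
                  apposition_contribution_pct =
                    round(apposition_contribution_pct, 1)))
  invisible(x)
}

#' Unrolled 2D map of the deployed skirt
#'
#' Projects each skirt element onto the unrolled (theta * r_ref, z) plane
#' for visualization. Areas reported by [summarize_sealing()] always come
#' from the 3D elements; this map is reporting-only.
#'
#' @param state a `deployed_state`.
#' @param records output of [sealing_records()] for the same state.
#' @return data.frame with 4 rows per element (polygon corners): columns
#'   `element_id`, `corner`, `u` (mm), `v` (mm), `region`, `apposed`.
#' @export
project_skirt_2d <- function(state, records) {
  frame <- state$frame
  nodes <- frame_nodes(frame)
  q <- frame$skirt_elements
  r_ref <- mean(sqrt(nodes[unique(as.vector(q)), 1]^2 +
                       nodes[unique(as.vector(q)), 2]^2))
  out <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    pts <- nodes[q[i, ], , drop = FALSE]
    th <- atan2(pts[, 2], pts[, 1])
    ## unwrap the seam: keep the 4 corners within half a turn of each other
    th <- th[1] + ((th - th[1] + pi) %% (2 * pi)) - pi
    out[[i]] <- data.frame(element_id = i, corner = 1:4,
                           u = th * r_ref, v = pts[, 3],
                           region = records$region[i],
                           apposed = records$apposed[i],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plot the 2D skirt map (requires ggplot2)
#'
#' @param map2d output of [project_skirt_2d()].
#' @param color `"apposition"` (apposed/malapposed) or `"region"`.
#' @return a ggplot object.
#' @export
plot_skirt_map <- function(map2d, color = c("apposition", "region")) {
  color <- match.arg(color)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  fill <- if (color == "apposition") factor(ifelse(map2d$apposed, "apposed",
                                                   "malapposed"))
          else factor(map2d$region)
  ggplot2::ggplot(map2d,
                  ggplot2::aes(x = .data$u, y = .data$v,
                               group = .data$element_id)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = fill), color = NA) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "unrolled circumference (mm)", y = "height (mm)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Surrogate paravalvular-leak grade from total skirt malapposition
#'
#' Maps the total malapposition percentage to a VARC-2-style grade:
#' `none_or_trace` below `t1`, `mild` below `t2`, `moderate` otherwise.
#' The default thresholds (10%, 25%) are calibration constants of this
#' package, not clinical values.
#'
#' @param summary a `sealing_summary` (or a bare malapposition percentage).
#' @param grade_thresholds numeric length-2, `t1 < t2`, in percent.
#' @return factor with levels `none_or_trace`, `mild`, `moderate`.
#' @export
pvl_surrogate <- function(summary, grade_thresholds = c(10, 25)) {
  t1 <- grade_thresholds[1]; t2 <- grade_thresholds[2]
  if (!(t1 < t2)) stop("grade thresholds must satisfy t1 < t2")
  pct <- if (inherits(summary, "sealing_summary"))
    summary$malapposition_total_pct else as.numeric(summary)
  grade <- ifelse(pct < t1, "none_or_trace", ifelse(pct < t2, "mild",
                                                    "moderate"))
  factor(grade, levels = c("none_or_trace", "mild", "moderate"))
}
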