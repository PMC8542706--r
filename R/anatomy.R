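## Parametric aortic-root generator: region-labeled tube meshes for
## tricuspid (TAV) and bicuspid (Sievers type 0 / type 1) morphologies.
##
## Coordinate convention: the annular plane is z = 0 with +z toward the
## aorta; the cylindrical angle theta is measured from a fixed commissure.
## All lengths in mm.

#' Parameters of a synthetic aortic root
#'
#' Defines a parametric, region-labeled aortic-root tube: an elliptical
#' annulus, a sinus bulge up to the sinotubular junction (STJ), leaflets
#' modeled as an inward bulged band of the inner surface (the innermost
#' surface a device skirt can contact), and interleaflet triangles as the
#' bare wall wedges between the scalloped leaflet attachment lines.
#'
#' @param morphology `"TAV"`, `"BAV0"` (Sievers type 0: two leaflets, no
#'   raphe) or `"BAV1"` (type 1: three developmental leaflets with two fused
#'   by a raphe).
#' @param annulus_dmax,annulus_dmin maximum/minimum annulus diameters (mm).
#' @param lvot_height extent of the left ventricular outflow tract below the
#'   annular plane (mm).
#' @param sinus_radius_factor peak sinus radius relative to the local
#'   annular radius (dimensionless, >= 1).
#' @param commissure_height height of the commissures above the annulus (mm).
#' @param stj_height height of the sinotubular junction (mm); the sinus
#'   bulge vanishes there.
#' @param ascending_height length of ascending aorta above the STJ (mm).
#' @param raphe_present logical; must be `TRUE` for BAV1 and `FALSE` for
#'   BAV0.
#' @param raphe_height_fraction raphe ridge height as a fraction of
#'   `commissure_height`.
#' @param calcium_deposits list of [calcium_deposit()] objects.
#' @param mesh_resolution integer length-2: circumferential and axial vertex
#'   counts (>= 24 and >= 12).
#' @param attachment_sharpness exponent of the leaflet attachment curve;
#'   larger values give narrower interleaflet triangles (default 3, a
#'   scalloped crown).
#' @param leaflet_bulge inward leaflet bulge amplitude as a fraction of the
#'   local annular radius (default 0.05; the stenotic leaflets form a
#'   near-cylindrical channel slightly inside the annulus).
#' @param raphe_protrusion inward protrusion of the BAV1 raphe ridge (mm).
#' @param ellipse_axis_angle orientation of the annular ellipse long axis
#'   (radians from the first commissure).
#' @return A validated list of class `root_params`.
#' @export
root_params <- function(morphology = c("TAV", "BAV0", "BAV1"),
                        annulus_dmax = 27, annulus_dmin = 22,
                        lvot_height = 12, sinus_radius_factor = 1.25,
                        commissure_height = 18, stj_height = 22,
                        ascending_height = 18,
                        raphe_present = NULL, raphe_height_fraction = 0.6,
                        calcium_deposits = list(),
                        mesh_resolution = c(96L, 60L),
                        attachment_sharpness = 3,
                        leaflet_bulge = 0.05,
                        raphe_protrusion = 3,
                        ellipse_axis_angle = 0) {
  morphology <- match.arg(morphology)
  if (is.null(raphe_present)) raphe_present <- identical(morphology, "BAV1")
  if (annulus_dmin > annulus_dmax) stop("annulus_dmin must be <= annulus_dmax")
  if (!(commissure_height < stj_height))
    stop("commissure_height must be below stj_height")
  if (ascending_height <= 0) stop("ascending_height must be > 0")
  if (sinus_radius_factor < 1) stop("sinus_radius_factor must be >= 1")
  if (morphology == "BAV0" && raphe_present)
    stop("BAV0 has no raphe (raphe_present must be FALSE)")
  if (morphology == "BAV1" && !raphe_present)
    stop("BAV1 requires raphe_present = TRUE")
  if (raphe_height_fraction < 0 || raphe_height_fraction > 1)
    stop("raphe_height_fraction must lie in [0, 1]")
  mesh_resolution <- as.integer(mesh_resolution)
  if (mesh_resolution[1] < 24) stop("circumferential_count must be >= 24")
  if (mesh_resolution[2] < 12) stop("axial_count must be >= 12")
  n_leaflets <- if (morphology == "BAV0") 2L else 3L
  if (mesh_resolution[1] / n_leaflets < 8)
    stop(sprintf(paste("mesh too coarse: %d circumferential vertices cannot",
                       "represent %d leaflets (need >= 8 per leaflet)"),
                 mesh_resolution[1], n_leaflets))
  structure(list(morphology = morphology,
                 annulus_dmax = annulus_dmax, annulus_dmin = annulus_dmin,
                 lvot_height = lvot_height,
                 sinus_radius_factor = sinus_radius_factor,
                 commissure_height = commissure_height,
                 stj_height = stj_height, ascending_height = ascending_height,
                 raphe_present = raphe_present,
                 raphe_height_fraction = raphe_height_fraction,
                 calcium_deposits = calcium_deposits,
                 mesh_resolution = mesh_resolution,
                 attachment_sharpness = attachment_sharpness,
                 leaflet_bulge = leaflet_bulge,
                 raphe_protrusion = raphe_protrusion,
                 ellipse_axis_angle = ellipse_axis_angle),
            class = "root_params")
}

#' A discrete calcification deposit on a leaflet
#'
#' @param center_angle,center_height deposit footprint centre (radians, mm).
#' @param extent_angle,extent_height footprint extents (radians, mm).
#' @param volume deposit volume (mm^3, > 0).
#' @param protrusion maximum inward displacement of affected triangles (mm).
#' @return list of class `calcium_deposit`.
#' @export
calcium_deposit <- function(center_angle, center_height,
                            extent_angle, extent_height,
                            volume, protrusion) {
  if (volume <= 0) stop("calcium volume must be > 0")
  if (protrusion < 0) stop("protrusion must be >= 0")
  if (extent_angle <= 0 || extent_height <= 0) stop("extents must be > 0")
  structure(list(center_angle = center_angle, center_height = center_height,
                 extent_angle = extent_angle, extent_height = extent_height,
                 volume = volume, protrusion = protrusion),
            class = "calcium_deposit")
}

## Commissure / nadir layout for a morphology; angles from the first
## commissure. BAV1 keeps the developmental three-commissure layout with the
## commissure at 240 degrees fused (its triangle becomes leaflet + raphe).
root_layout <- function(morphology) {
  switch(morphology,
    TAV  = list(commissures = c(0, 2, 4) * pi / 3, fused = NA_real_),
    BAV0 = list(commissures = c(0, pi), fused = NA_real_),
    BAV1 = list(commissures = c(0, 2, 4) * pi / 3, fused = 4 * pi / 3))
}

## Leaflet attachment height at angle theta: ch * u^q with u ramping from 0
## at the nadirs to 1 at the commissures. Below the curve lies the
## interleaflet triangle (apex at the commissure top, base on the annulus).
attachment_height <- function(theta, commissures, ch, q) {
  w <- pi / length(commissures)              # commissure-to-nadir half width
  d <- vapply(theta, function(th) min(angle_diff(th, commissures)), numeric(1))
  u <- pmax(0, 1 - d / w)
  ch * u^q
}

## Inner-surface radius of the root at (theta, z), before calcium.
root_radius <- function(theta, z, p, layout) {
  a <- p$annulus_dmax / 2
  b <- p$annulus_dmin / 2
  r_ann <- ellipse_radius(theta - p$ellipse_axis_angle, a, b)
  bump <- ifelse(z > 0 & z < p$stj_height, sin(pi * z / p$stj_height), 0)
  r <- r_ann * (1 + (p$sinus_radius_factor - 1) * bump)
  ## leaflet zone: supra-annular band above the attachment curve
  h_att <- attachment_height(theta, layout$commissures, p$commissure_height,
                             p$attachment_sharpness)
  in_band <- z >= 0 & z <= p$commissure_height
  fused_zone <- rep(FALSE, length(theta))
  if (!is.na(layout$fused)) {
    w <- pi / length(layout$commissures)
    fused_zone <- in_band & angle_diff(theta, layout$fused) < w &
      z < h_att
  }
  leaflet <- (in_band & z >= h_att) | fused_zone
  r_leaf <- r_ann * (1 - p$leaflet_bulge * sin(pi * pmax(z, 0) /
                                                 p$commissure_height))
  r <- ifelse(leaflet, pmin(r, r_leaf), r)
  ## raphe ridge along the fused commissure (BAV1)
  if (!is.na(layout$fused) && p$raphe_present) {
    rh <- p$raphe_height_fraction * p$commissure_height
    on_raphe <- angle_diff(theta, layout$fused) < 0.12 & z >= 0 & z <= rh
    ridge <- p$raphe_protrusion * sin(pi * pmax(z, 0) / max(rh, 1e-9))
    r <- ifelse(on_raphe, r - ridge, r)
  }
  r
}

## Region label at a surface point (theta, z).
root_region <- function(theta, z, p, layout) {
  h_att <- attachment_height(theta, layout$commissures, p$commissure_height,
                             p$attachment_sharpness)
  reg <- rep("ASCENDING_AORTA", length(theta))
  reg[z < 0] <- "LVOT"
  band <- z >= 0 & z <= p$commissure_height
  reg[band & z >= h_att] <- "LEAFLET"
  reg[band & z < h_att] <- "INTERLEAFLET_TRIANGLE"
  if (!is.na(layout$fused)) {
    w <- pi / length(layout$commissures)
    fused <- band & z < h_att & angle_diff(theta, layout$fused) < w
    reg[fused] <- "LEAFLET"                  # fusion removes this triangle
  }
  reg
}

#' Build a region-labeled aortic-root surface mesh
#'
#' Generates the inner surface of the aortic root as a structured tube mesh
#' (open at the ventricular inlet and aortic outlet) with per-triangle
#' anatomical region labels (`LVOT`, `LEAFLET`, `INTERLEAFLET_TRIANGLE`,
#' `ASCENDING_AORTA`) and material ids, then applies any calcium deposits in
#' `params$calcium_deposits` via [place_calcium()].
#'
#' @param params a [root_params()] object.
#' @return An object of classes `aortic_root` and `surface_mesh`, with the
#'   generating parameters in `attr(,"params")`.
#' @export
build_root <- function(params) {
  stopifnot(inherits(params, "root_params"))
  p <- params
  layout <- root_layout(p$morphology)
  nc <- p$mesh_resolution[1]
  nz <- p$mesh_resolution[2]
  z_top <- p$stj_height + p$ascending_height
  ## axial rows: proportional split below/above the annulus, z = 0 included
  n_lvot <- max(3L, round(nz * p$lvot_height / (p$lvot_height + z_top)))
  z_rows <- unique(c(seq(-p$lvot_height, 0, length.out = n_lvot + 1),
                     seq(0, z_top, length.out = nz - n_lvot + 1)))
  theta <- 2 * pi * (seq_len(nc) - 1) / nc
  nrow_z <- length(z_rows)
  ## structured vertex grid
  th_grid <- rep(theta, times = nrow_z)
  z_grid <- rep(z_rows, each = nc)
  r_grid <- root_radius(th_grid, z_grid, p, layout)
  vertices <- cbind(r_grid * cos(th_grid), r_grid * sin(th_grid), z_grid)
  ## two triangles per quad cell, wrapping circumferentially
  idx <- function(i, j) (j - 1L) * nc + ((i - 1L) %% nc) + 1L
  i_seq <- rep(seq_len(nc), times = nrow_z - 1L)
  j_seq <- rep(seq_len(nrow_z - 1L), each = nc)
  v00 <- idx(i_seq, j_seq)
  v10 <- idx(i_seq + 1L, j_seq)
  v01 <- idx(i_seq, j_seq + 1L)
  v11 <- idx(i_seq + 1L, j_seq + 1L)
  triangles <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  ## label triangles at their centroid in (theta, z)
  ctr_z <- (vertices[triangles[, 1], 3] + vertices[triangles[, 2], 3] +
              vertices[triangles[, 3], 3]) / 3
  ctr_x <- (vertices[triangles[, 1], 1] + vertices[triangles[, 2], 1] +
              vertices[triangles[, 3], 1]) / 3
  ctr_y <- (vertices[triangles[, 1], 2] + vertices[triangles[, 2], 2] +
              vertices[triangles[, 3], 2]) / 3
  ctr_th <- wrap_angle(atan2(ctr_y, ctr_x))
  region <- root_region(ctr_th, ctr_z, p, layout)
  material <- ifelse(region == "LEAFLET", "LEAFLET_TISSUE", "WALL")
  mesh <- surface_mesh(vertices, triangles, region, material)
  class(mesh) <- c("aortic_root", class(mesh))
  attr(mesh, "params") <- p
  attr(mesh, "layout") <- layout
  if (length(p$calcium_deposits) > 0)
    mesh <- place_calcium(mesh, p$calcium_deposits)
  mesh
}

#' Cross-section polygon of a mesh at height z
#'
#' Slices every triangle with the plane `z = const` and returns the
#' intersection points ordered by angle about the section centroid.
#'
#' @param mesh a `surface_mesh`.
#' @param z section height (mm).
#' @return two-column matrix (x, y) of ordered polygon vertices.
#' @export
mesh_cross_section <- function(mesh, z) {
  v <- mesh$vertices
  tr <- mesh$triangles
  zs <- matrix(v[t(tr), 3], ncol = 3, byrow = TRUE)
  crossing <- (apply(zs, 1, min) <= z) & (apply(zs, 1, max) >= z)
  if (!any(crossing)) stop("plane z = ", z, " does not intersect the mesh")
  pts <- list()
  for (k in which(crossing)) {
    tv <- v[tr[k, ], , drop = FALSE]
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      z1 <- tv[e[1], 3]; z2 <- tv[e[2], 3]
      if ((z1 - z) * (z2 - z) <= 0 && z1 != z2) {
        s <- (z - z1) / (z2 - z1)
        pts[[length(pts) + 1L]] <- tv[e[1], 1:2] +
          s * (tv[e[2], 1:2] - tv[e[1], 1:2])
      } else if (z1 == z && z2 == z) {
        pts[[length(pts) + 1L]] <- tv[e[1], 1:2]
        pts[[length(pts) + 1L]] <- tv[e[2], 1:2]
      }
    }
  }
  xy <- do.call(rbind, pts)
  xy <- unique(round(xy, 9))
  ctr <- colMeans(xy)
  ord <- order(atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1]))
  xy[ord, , drop = FALSE]
}

#' Annulus metrics of an aortic root
#'
#' Measures the annular (z = 0) cross-section: maximum and minimum diameter
#' and the perimeter- and area-derived diameters used for device sizing
#' (P/pi and 2*sqrt(A/pi)).
#'
#' @param mesh an `aortic_root` (or any `surface_mesh` crossing z = 0).
#' @return named numeric vector with `dmax`, `dmin`, `perimeter_diam`,
#'   `area_diam` (mm).
#' @export
annulus_metrics <- function(mesh) {
  xy <- mesh_cross_section(mesh, 0)
  c(dmax = polygon_dmax(xy),
    dmin = polygon_dmin(xy),
    perimeter_diam = polygon_perimeter(xy) / pi,
    area_diam = 2 * sqrt(polygon_area(xy) / pi))
}

#' Apply calcium deposits to leaflet regions of a root mesh
#'
#' Triangles whose centroid falls inside a deposit footprint (and carry a
#' `LEAFLET` region label) are re-assigned material `CALCIUM` and displaced
#' radially inward by `volume / footprint_area`, capped at the deposit's
#' `protrusion`, so that the assigned volume (sum of footprint area times
#' displacement) tracks the requested volume.
#'
#' @param mesh an `aortic_root`.
#' @param deposits list of [calcium_deposit()] objects.
#' @return The modified mesh; assigned volumes in
#'   `attr(,"calcium_assigned")`.
#' @export
place_calcium <- function(mesh, deposits) {
  if (length(deposits) == 0) return(mesh)
  v <- mesh$vertices
  tr <- mesh$triangles
  ctr_x <- (v[tr[, 1], 1] + v[tr[, 2], 1] + v[tr[, 3], 1]) / 3
  ctr_y <- (v[tr[, 1], 2] + v[tr[, 2], 2] + v[tr[, 3], 2]) / 3
  ctr_z <- (v[tr[, 1], 3] + v[tr[, 2], 3] + v[tr[, 3], 3]) / 3
  ctr_th <- atan2(ctr_y, ctr_x)
  areas <- triangle_areas(mesh)
  assigned <- numeric(length(deposits))
  ## overlapping deposits do not stack: per-vertex inward displacement is
  ## the maximum over deposits (a nodule's thickness, not a sum), and the
  ## lumen keeps a stenotic floor radius
  vdisp <- numeric(nrow(v))
  floor_radius <- 4.5
  for (di in seq_along(deposits)) {
    d <- deposits[[di]]
    stopifnot(inherits(d, "calcium_deposit"))
    foot <- angle_diff(ctr_th, d$center_angle) <= d$extent_angle / 2 &
      abs(ctr_z - d$center_height) <= d$extent_height / 2
    if (!any(foot))
      stop("calcium deposit ", di, " has an empty footprint")
    if (!any(mesh$region[foot] == "LEAFLET"))
      stop("calcium deposit ", di, " footprint lies off the leaflet region")
    foot <- foot & mesh$region == "LEAFLET"
    a_foot <- sum(areas[foot])
    p_eff <- min(d$volume / a_foot, d$protrusion)
    assigned[di] <- a_foot * p_eff
    mesh$material[foot] <- "CALCIUM"
    vid <- unique(as.vector(tr[foot, ]))
    vdisp[vid] <- pmax(vdisp[vid], p_eff)
  }
  moved <- which(vdisp > 0)
  if (length(moved) > 0) {
    rad <- sqrt(v[moved, 1]^2 + v[moved, 2]^2)
    shrink <- pmax(rad - vdisp[moved], floor_radius) / rad
    v[moved, 1] <- v[moved, 1] * shrink
    v[moved, 2] <- v[moved, 2] * shrink
  }
  mesh$vertices <- v
  attr(mesh, "query_cache") <- NULL
  attr(mesh, "calcium_assigned") <- assigned
  mesh
}

#' Count disjoint patches of a region label
#'
#' Triangles sharing at least one vertex and carrying the same label form a
#' patch; used to check morphology cardinality (3 interleaflet triangles for
#' TAV, 2 for BAV0 and BAV1).
#'
#' @param mesh a `surface_mesh`.
#' @param label region label to count.
#' @return integer patch count.
#' @export
region_patch_count <- function(mesh, label = "INTERLEAFLET_TRIANGLE") {
  sel <- which(mesh$region == label)
  if (length(sel) == 0) return(0L)
  tr <- mesh$triangles[sel, , drop = FALSE]
  parent <- seq_along(sel)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  by_vertex <- split(rep(seq_along(sel), 3), as.vector(tr))
  for (grp in by_vertex) {
    if (length(grp) > 1) {
      r1 <- find(grp[1])
      for (g in grp[-1]) { r2 <- find(g); if (r1 != r2) parent[r2] <- r1 }
    }
  }
  length(unique(vapply(seq_along(sel), find, integer(1))))
}
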