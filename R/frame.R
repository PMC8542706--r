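## Parametric self-expanding frame: diamond-cell lattice with a flared
## inflow profile and a fabric skirt over its lower portion, plus the
## virtual radial-force bench (loading/unloading hysteresis).

#' Default nominal profile for a device size
#'
#' Flared inflow at the nominal size, a constrained waist at 55% of frame
#' height, and a moderately flared outflow. Heights in mm from the
#' ventricular end; radii in mm.
#' @param size_label device size (23, 26, 29 or 32 mm).
#' @return data.frame with columns `height`, `radius`.
#' @export
default_profile <- function(size_label) {
  h <- size_label + 24                      # frame height grows with size
  data.frame(height = c(0, 0.25, 0.55, 1) * h,
             radius = c(size_label / 2, size_label / 2 - 0.5,
                        size_label / 2 - 3, size_label / 2 - 2))
}

#' Parameters of a parametric self-expanding frame
#'
#' @param size_label nominal device size in mm: 23, 26, 29 or 32.
#' @param nominal_profile data.frame `height`/`radius` (mm), heights strictly
#'   increasing; defaults to [default_profile()].
#' @param n_levels,n_sectors node-grid resolution (`n_sectors` must be even
#'   for diamond cells).
#' @param circumferential_stiffness radial-force scale: Newtons per level
#'   per unit circumferential strain.
#' @param inter_level_stiffness reserved coupling stiffness (stored; the
#'   radial bench law is per-level).
#' @param expansion_pressure frame expansion pressure scale (MPa) at full
#'   crimp strain, used by the deployment solver.
#' @param skirt_height skirt coverage from the ventricular end (mm);
#'   defaults to 40% of frame height.
#' @param hysteresis_factor multiplicative unloading factor in (0, 1].
#' @param angle_offset azimuthal offset of the node grid (radians).
#' @return list of class `frame_params`.
#' @export
frame_params <- function(size_label = 26, nominal_profile = NULL,
                         n_levels = 40L, n_sectors = 32L,
                         circumferential_stiffness = 5,
                         inter_level_stiffness = 1,
                         expansion_pressure = 0.5,
                         skirt_height = NULL,
                         hysteresis_factor = 0.8,
                         angle_offset = 0.013) {
  if (!size_label %in% DEVICE_SIZES)
    stop("size_label must be one of ", paste(DEVICE_SIZES, collapse = ", "))
  if (is.null(nominal_profile)) nominal_profile <- default_profile(size_label)
  if (any(diff(nominal_profile$height) <= 0))
    stop("profile heights must be strictly increasing")
  if (any(nominal_profile$radius <= 0)) stop("profile radii must be > 0")
  if (n_sectors %% 2 != 0) stop("n_sectors must be even (diamond cells)")
  if (hysteresis_factor <= 0 || hysteresis_factor > 1)
    stop("hysteresis_factor must lie in (0, 1]")
  frame_h <- max(nominal_profile$height)
  if (is.null(skirt_height)) skirt_height <- 0.4 * frame_h
  if (skirt_height > frame_h) stop("skirt_height exceeds frame height")
  structure(list(size_label = size_label, nominal_profile = nominal_profile,
                 n_levels = as.integer(n_levels),
                 n_sectors = as.integer(n_sectors),
                 circumferential_stiffness = circumferential_stiffness,
                 inter_level_stiffness = inter_level_stiffness,
                 expansion_pressure = expansion_pressure,
                 skirt_height = skirt_height,
                 hysteresis_factor = hysteresis_factor,
                 angle_offset = angle_offset),
            class = "frame_params")
}

#' Build a frame node grid with struts and skirt elements
#'
#' Nodes form a `n_levels x n_sectors` cylindrical grid following the
#' nominal profile; struts are the two diagonal families between adjacent
#' levels (diamond cells) plus closing rings at both ends; quadrilateral
#' skirt elements cover all cells whose levels lie at or below
#' `skirt_height`.
#'
#' @param params a [frame_params()].
#' @return list of class `frame_mesh`: `radii` and `angles`
#'   (`n_levels x n_sectors` matrices), `heights` (per level, mm from the
#'   ventricular end), `z` (per level, mm in anatomy coordinates; equals
#'   `heights` until deployment), `struts` (2-column node-id matrix),
#'   `skirt_elements` (4-column node-id matrix), `reference_radii` (nominal
#'   per-level radii), `params`.
#' @export
build_frame <- function(params) {
  stopifnot(inherits(params, "frame_params"))
  nl <- params$n_levels; ns <- params$n_sectors
  heights <- seq(0, max(params$nominal_profile$height), length.out = nl)
  r_nom <- interp_profile(heights, params$nominal_profile$height,
                          params$nominal_profile$radius)
  angles <- matrix(rep(2 * pi * (seq_len(ns) - 1) / ns + params$angle_offset,
                       each = nl), nl, ns)
  radii <- matrix(rep(r_nom, ns), nl, ns)
  nid <- function(l, s) (((s - 1) %% ns)) * nl + l
  l_seq <- rep(seq_len(nl - 1L), ns)
  s_seq <- rep(seq_len(ns), each = nl - 1L)
  struts <- rbind(cbind(nid(l_seq, s_seq), nid(l_seq + 1L, s_seq + 1L)),
                  cbind(nid(l_seq, s_seq), nid(l_seq + 1L, s_seq - 1L)),
                  cbind(nid(1L, seq_len(ns)), nid(1L, seq_len(ns) + 1L)),
                  cbind(nid(nl, seq_len(ns)), nid(nl, seq_len(ns) + 1L)))
  skirt_levels <- which(heights <= params$skirt_height + 1e-9)
  sk_l <- skirt_levels[-length(skirt_levels)]
  sl <- rep(sk_l, ns)
  ss <- rep(seq_len(ns), each = length(sk_l))
  skirt <- cbind(nid(sl, ss), nid(sl, ss + 1L),
                 nid(sl + 1L, ss + 1L), nid(sl + 1L, ss))
  structure(list(radii = radii, angles = angles, heights = heights,
                 z = heights, struts = struts, skirt_elements = skirt,
                 reference_radii = r_nom, params = params),
            class = "frame_mesh")
}

#' @export
print.frame_mesh <- function(x, ...) {
  cat("frame_mesh: size", x$params$size_label, "mm,",
      x$params$n_levels, "levels x", x$params$n_sectors, "sectors;",
      nrow(x$struts), "struts,", nrow(x$skirt_elements), "skirt elements\n")
  invisible(x)
}

#' Node coordinates of a frame as an (n_nodes x 3) matrix
#'
#' Node id convention: `id = (sector - 1) * n_levels + level`.
#' @param frame a `frame_mesh`.
#' @export
frame_nodes <- function(frame) {
  x <- as.vector(frame$radii * cos(frame$angles))
  y <- as.vector(frame$radii * sin(frame$angles))
  z <- rep(frame$z, ncol(frame$radii))
  cbind(x = x, y = y, z = z)
}

#' Crimp a frame to a target diameter
#'
#' Radius-only: all node radii are set to `target_diameter / 2`; angles,
#' heights and the nominal reference state are untouched.
#'
#' @param frame a `frame_mesh`.
#' @param target_diameter crimped diameter (mm), below the smallest nominal
#'   diameter.
#' @return The crimped `frame_mesh`.
#' @export
crimp <- function(frame, target_diameter) {
  stopifnot(inherits(frame, "frame_mesh"))
  if (target_diameter <= 0) stop("target_diameter must be > 0")
  if (target_diameter >= 2 * min(frame$reference_radii))
    stop("target_diameter must be below the minimum nominal diameter")
  frame$radii[] <- target_diameter / 2
  frame
}

#' Restore a frame to its nominal reference geometry
#' @param frame a `frame_mesh`.
#' @export
frame_restore <- function(frame) {
  frame$radii <- matrix(rep(frame$reference_radii, ncol(frame$radii)),
                        nrow(frame$radii), ncol(frame$radii))
  frame$z <- frame$heights
  frame
}

#' Radial force of a frame held at a uniform diameter
#'
#' Per-level linear spring law: each level contributes
#' `circumferential_stiffness * max(0, (r_nom - r) / r_nom)` Newtons; the
#' total is multiplied by `hysteresis_factor` during unloading. Zero at the
#' nominal (maximum) diameter and monotone non-increasing in diameter.
#'
#' @param params a [frame_params()].
#' @param diameter crimper diameter (mm), `0 < diameter <= nominal`.
#' @param phase `"loading"` or `"unloading"`.
#' @return force in N.
#' @export
radial_force <- function(params, diameter, phase = c("loading", "unloading")) {
  phase <- match.arg(phase)
  stopifnot(inherits(params, "frame_params"))
  nominal <- 2 * max(params$nominal_profile$radius)
  if (diameter <= 0) stop("diameter must be > 0")
  if (diameter > nominal + 1e-9) stop("diameter exceeds nominal diameter")
  heights <- seq(0, max(params$nominal_profile$height),
                 length.out = params$n_levels)
  r_nom <- interp_profile(heights, params$nominal_profile$height,
                          params$nominal_profile$radius)
  strain <- pmax(0, (r_nom - diameter / 2) / r_nom)
  f <- params$circumferential_stiffness * sum(strain)
  if (phase == "unloading") f <- f * params$hysteresis_factor
  f
}

#' Virtual radial-force bench test
#'
#' Sweeps the crimper from the nominal diameter down to `min_diameter`
#' (loading) and back (unloading), evaluating [radial_force()] in each
#' phase.
#'
#' @param params a [frame_params()].
#' @param min_diameter smallest crimper diameter (mm).
#' @param n_steps number of diameters per phase (>= 2).
#' @return list of class `radial_force_curve`: `diameters` (descending then
#'   ascending), `loading_force`, `unloading_force` (both evaluated on the
#'   full sweep).
#' @export
virtual_bench_test <- function(params, min_diameter, n_steps = 25) {
  stopifnot(inherits(params, "frame_params"))
  nominal <- 2 * max(params$nominal_profile$radius)
  if (min_diameter >= nominal) stop("min_diameter must be below nominal")
  if (n_steps < 2) stop("n_steps must be >= 2")
  down <- seq(nominal, min_diameter, length.out = n_steps)
  up <- rev(down)[-1]
  diameters <- c(down, up)
  structure(list(
    diameters = diameters,
    loading_force = vapply(diameters, radial_force, numeric(1),
                           params = params, phase = "loading"),
    unloading_force = vapply(diameters, radial_force, numeric(1),
                             params = params, phase = "unloading")),
    class = "radial_force_curve")
}
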