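## Quasi-static deployment: per-node radial equilibrium of the released
## frame against region-dependent tissue resistance, with sequential level
## release from the ventricular end. Contact is normal-ray based: each node
## sees the anatomy lumen radius along its own radial ray.

#' Linear-elastic tissue description
#'
#' Material constants follow the calibrated linear models used for TAVR
#' simulation: aortic wall E = 2 MPa / 2 mm, leaflets E = 0.6 MPa / 1.5 mm,
#' calcium E = 4 MPa with perfect plasticity at 0.6 MPa.
#'
#' @param elastic_modulus E in MPa (> 0).
#' @param thickness shell thickness in mm (> 0).
#' @param yield_stress optional perfect-plasticity cap in MPa.
#' @return list of class `tissue_material`.
#' @export
tissue_material <- function(elastic_modulus, thickness, yield_stress = NULL) {
  if (elastic_modulus <= 0) stop("elastic_modulus must be > 0")
  if (thickness <= 0) stop("thickness must be > 0")
  if (!is.null(yield_stress) && yield_stress <= 0)
    stop("yield_stress must be > 0 when present")
  structure(list(elastic_modulus = elastic_modulus, thickness = thickness,
                 yield_stress = yield_stress), class = "tissue_material")
}

#' Default material map (by material id)
#' @return named list of [tissue_material()]: `WALL`, `LEAFLET_TISSUE`,
#'   `CALCIUM`.
#' @export
default_materials <- function() {
  list(WALL = tissue_material(2, 2),
       LEAFLET_TISSUE = tissue_material(0.6, 1.5),
       CALCIUM = tissue_material(4, 2, yield_stress = 0.6))
}

#' Contact / solver parameters for deployment
#'
#' @param friction_coefficient stored and reported (0.7); the axial position
#'   is prescribed, so no axial slip is simulated.
#' @param penalty_exponent exponent of the contact penalty (1 = linear).
#' @param max_ray_length maximum contact-ray length (mm).
#' @param release_schedule only `"ventricular_first"` is implemented.
#' @param residual_tol convergence tolerance on the pressure imbalance (MPa).
#' @param max_iterations per-node iteration cap.
#' @param damping fixed-point damping factor.
#' @return list of class `contact_params`.
#' @export
contact_params <- function(friction_coefficient = 0.7, penalty_exponent = 1,
                           max_ray_length = 30,
                           release_schedule = "ventricular_first",
                           residual_tol = 1e-6, max_iterations = 200,
                           damping = 0.5) {
  if (residual_tol <= 0) stop("residual_tol must be > 0")
  if (max_ray_length <= 0) stop("max_ray_length must be > 0")
  release_schedule <- match.arg(release_schedule, "ventricular_first")
  structure(list(friction_coefficient = friction_coefficient,
                 penalty_exponent = penalty_exponent,
                 max_ray_length = max_ray_length,
                 release_schedule = release_schedule,
                 residual_tol = residual_tol,
                 max_iterations = as.integer(max_iterations),
                 damping = damping),
            class = "contact_params")
}

#' Thin-shell radial tissue stiffness
#'
#' Contact pressure per unit radial displacement of a thin elastic shell:
#' `E * t / r^2` (MPa/mm). For materials with a yield stress the contact
#' pressure is capped there (perfect plasticity) — the cap is applied by the
#' contact solver, not here.
#'
#' @param material a [tissue_material()].
#' @param local_radius local lumen radius r (mm, > 0).
#' @return stiffness in MPa/mm.
#' @export
tissue_stiffness <- function(material, local_radius) {
  stopifnot(inherits(material, "tissue_material"))
  if (local_radius <= 0) stop("local_radius must be > 0")
  material$elastic_modulus * material$thickness / local_radius^2
}

## Contact pressure of a tissue at penetration delta (>= 0), with optional
## plastic cap and penalty exponent.
contact_pressure <- function(delta, k_t, yield, expn = 1) {
  p <- k_t * pmax(delta, 0)^expn
  if (!is.null(yield)) p <- pmin(p, yield)
  p
}

## Frame expansion pressure at radius r for nominal radius r_nom:
## linear in the recoverable strain, zero at nominal.
frame_pressure <- function(r, r_nom, scale) {
  scale * pmax(r_nom - r, 0) / r_nom
}

## Solve one node's radial equilibrium. For the default linear penalty the
## balance is piecewise linear and solved in closed form (elastic branch,
## perfect-plastic branch, or tissue bottoming out at its thickness — an
## active constraint with zero residual). Nonlinear penalty exponents use a
## damped fixed-point iteration.
solve_node <- function(r_nom, r_a, k_t, yield, thickness, scale,
                       contact) {
  if (r_nom <= r_a) {
    return(list(r = r_nom, pressure = 0, iterations = 0L, residual = 0))
  }
  finish <- function(r, it) {
    r <- min(max(r, r_a), r_nom)
    bottomed <- (r - r_a) >= thickness - 1e-12
    if (bottomed) r <- r_a + thickness
    pf <- frame_pressure(r, r_nom, scale)
    pt <- contact_pressure(r - r_a, k_t, yield, contact$penalty_exponent)
    list(r = r, pressure = pf, iterations = it,
         residual = if (bottomed) 0 else abs(pf - pt))
  }
  if (contact$penalty_exponent == 1) {
    r_e <- (scale + k_t * r_a) / (k_t + scale / r_nom)
    d_e <- r_e - r_a
    if (!is.null(yield) && k_t * d_e > yield) {
      ## plastic branch: frame pressure balances the yield cap
      r_e <- if (scale > yield) r_nom * (1 - yield / scale) else r_nom
    }
    return(finish(r_e, 1L))
  }
  r <- r_a
  res <- Inf
  it <- 0L
  while (it < contact$max_iterations) {
    it <- it + 1L
    pf <- frame_pressure(r, r_nom, scale)
    pt <- contact_pressure(r - r_a, k_t, yield, contact$penalty_exponent)
    res <- pf - pt
    if (abs(res) <= contact$residual_tol) break
    slope <- scale / r_nom +
      contact$penalty_exponent * k_t * max(r - r_a, 1e-6)^
        (contact$penalty_exponent - 1)
    r <- min(max(r + contact$damping * res / slope, r_a), r_nom)
    if (r - r_a >= thickness) break
  }
  finish(r, it)
}

#' Deploy a crimped frame inside an aortic root
#'
#' Releases the frame level by level from the ventricular end. Each node
#' expands radially until its expansion pressure balances the local tissue
#' contact pressure (linear penalty on penetration, perfect-plastic cap for
#' calcium) or it reaches its nominal radius (free expansion). Contacted
#' anatomy triangles are displaced outward by the first-order compliance
#' `pressure / stiffness`, capped at the tissue thickness.
#'
#' @param frame a crimped `frame_mesh`.
#' @param anatomy an `aortic_root`.
#' @param depth implantation depth: annular plane to frame ventricular end
#'   (mm).
#' @param contact a [contact_params()].
#' @param materials named list of [tissue_material()] keyed by material id,
#'   as from [default_materials()].
#' @return list of class `deployed_state`: deformed `frame`, deformed
#'   `anatomy`, `depth`, `contact_record` (one row per node), `convergence`
#'   (iterations, final residual).
#' @export
deploy <- function(frame, anatomy, depth,
                   contact = contact_params(),
                   materials = default_materials()) {
  stopifnot(inherits(frame, "frame_mesh"), inherits(anatomy, "surface_mesh"))
  nl <- nrow(frame$radii); ns <- ncol(frame$radii)
  frame$z <- frame$heights - depth
  anatomy <- prepare_mesh(anatomy)
  scale <- frame$params$expansion_pressure
  ## lumen radius along each node's radial ray (constant per sector/level)
  r_anat <- matrix(Inf, nl, ns)
  hit_tri <- matrix(NA_integer_, nl, ns)
  for (l in seq_len(nl)) {
    z <- frame$z[l]
    for (s in seq_len(ns)) {
      th <- frame$angles[l, s]
      hit <- ray_first_hit(anatomy, c(0, 0, z), c(cos(th), sin(th), 0),
                           tmax = contact$max_ray_length)
      if (hit$hit) { r_anat[l, s] <- hit$t; hit_tri[l, s] <- hit$triangle }
    }
  }
  contacted <- is.finite(r_anat)
  if (any(frame$radii[contacted] >= r_anat[contacted] - 1e-9))
    stop("crimped frame does not fit inside the anatomy at depth ", depth)
  release_order <- seq_len(nl)                # ventricular end first
  n_nodes <- nl * ns
  out_r <- out_press <- numeric(n_nodes)
  out_reg <- out_mat <- character(n_nodes)
  max_res <- 0; tot_it <- 0L
  for (l in release_order) {
    r_nom <- frame$reference_radii[l]
    for (s in seq_len(ns)) {
      k <- (s - 1) * nl + l
      ra <- r_anat[l, s]
      if (!is.finite(ra)) {
        frame$radii[l, s] <- r_nom
        out_r[k] <- r_nom; out_press[k] <- 0
        out_reg[k] <- "NONE"; out_mat[k] <- "NONE"
        next
      }
      tri <- hit_tri[l, s]
      mat_id <- anatomy$material[tri]
      mat <- materials[[mat_id]]
      if (is.null(mat)) stop("no material defined for id ", mat_id)
      k_t <- tissue_stiffness(mat, ra)
      sol <- solve_node(r_nom, ra, k_t, mat$yield_stress, mat$thickness,
                        scale, contact)
      frame$radii[l, s] <- sol$r
      max_res <- max(max_res, sol$residual)
      tot_it <- tot_it + sol$iterations
      out_r[k] <- sol$r; out_press[k] <- sol$pressure
      out_reg[k] <- anatomy$region[tri]; out_mat[k] <- mat_id
    }
  }
  lev_vec <- rep(seq_len(nl), ns)
  sec_vec <- rep(seq_len(ns), each = nl)
  ra_vec <- r_anat[cbind(lev_vec, sec_vec)]
  ra_vec[!is.finite(ra_vec)] <- NA_real_
  record <- data.frame(
    level = lev_vec, sector = sec_vec,
    r_nominal = frame$reference_radii[lev_vec],
    r_deployed = out_r, r_anatomy = ra_vec,
    gap = pmax(ra_vec - out_r, 0),
    penetration = pmax(out_r - ra_vec, 0),
    pressure = out_press, region = out_reg, material = out_mat,
    stringsAsFactors = FALSE)
  record$penetration[is.na(record$penetration)] <- 0
  if (max_res > contact$residual_tol)
    stop("deployment did not converge: max residual ", signif(max_res, 4),
         " MPa exceeds tolerance ", contact$residual_tol)
  ## first-order anatomy compliance: displace contacted triangles outward
  disp <- numeric(nrow(anatomy$triangles))
  pen <- record$penetration > 0
  if (any(pen)) {
    idx <- hit_tri[cbind(record$level[pen], record$sector[pen])]
    for (k in seq_along(idx)) disp[idx[k]] <- max(disp[idx[k]],
                                                  record$penetration[pen][k])
    vdisp <- numeric(nrow(anatomy$vertices))
    moved <- which(disp > 0)
    for (t in moved) {
      vv <- anatomy$triangles[t, ]
      vdisp[vv] <- pmax(vdisp[vv], disp[t])
    }
    vm <- which(vdisp > 0)
    rad <- sqrt(anatomy$vertices[vm, 1]^2 + anatomy$vertices[vm, 2]^2)
    grow <- (rad + vdisp[vm]) / rad
    anatomy$vertices[vm, 1] <- anatomy$vertices[vm, 1] * grow
    anatomy$vertices[vm, 2] <- anatomy$vertices[vm, 2] * grow
    attr(anatomy, "query_cache") <- NULL
    anatomy <- prepare_mesh(anatomy)
  }
  structure(list(frame = frame, anatomy = anatomy, depth = depth,
                 contact_record = record,
                 convergence = list(iterations = tot_it,
                                    final_residual = max_res),
                 contact = contact, materials = materials),
            class = "deployed_state")
}

#' @export
print.deployed_state <- function(x, ...) {
  cat("deployed_state: size", x$frame$params$size_label, "mm at depth",
      round(x$depth, 2), "mm; residual",
      signif(x$convergence$final_residual, 3), "MPa\n")
  invisible(x)
}

#' Deploy while matching a target implantation depth
#'
#' Repeats [deploy()] with adjusted axial placement until the achieved depth
#' (annular plane to frame ventricular end) is within 0.1 mm of the target.
#' The radial solver prescribes the axial position, so this converges in one
#' outer iteration; the loop mirrors the depth-matching procedure used
#' against post-operative imaging and guards any future solver with axial
#' motion.
#'
#' @inheritParams deploy
#' @param target_depth requested implantation depth (mm, >= 0).
#' @param max_outer outer iteration cap.
#' @return a `deployed_state` with achieved depth within 0.1 mm of target.
#' @export
match_depth <- function(frame, anatomy, target_depth,
                        contact = contact_params(),
                        materials = default_materials(),
                        max_outer = 10) {
  if (target_depth < 0) stop("target_depth must be >= 0")
  offset <- target_depth
  for (i in seq_len(max_outer)) {
    state <- deploy(frame, anatomy, offset, contact, materials)
    achieved <- -min(state$frame$z)
    err <- target_depth - achieved
    if (abs(err) <= 0.1) {
      state$depth <- achieved
      return(state)
    }
    offset <- offset + err
  }
  stop("match_depth failed to reach ", target_depth, " mm within ",
       max_outer, " iterations")
}
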