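## Seeded synthetic cohort generator emulating the study population:
## per-morphology covariate distributions (annulus dimensions, calcium
## volume, implantation depth) given as truncated normals parameterised from
## the published group summaries, plus the clinical device-sizing rule.

DEVICE_SIZES <- c(23, 26, 29, 32)

#' Default per-morphology covariate distributions
#'
#' Truncated-normal parameters `c(mean, sd, lower, upper)` for the annulus
#' diameters, calcium volume and implantation depth of each morphology, and
#' the per-morphology device sizing target (minimum size / perimeter-derived
#' diameter ratio). Means and SDs follow the published per-group baseline
#' characteristics; bounds are physiologic.
#'
#' @return named list (`TAV`, `BAV0`, `BAV1`).
#' @export
default_covariates <- function() {
  list(
    TAV = list(annulus_dmax = c(27.4, 3.2, 22, 34),
               annulus_dmin = c(21.1, 2.3, 17, 28),
               calcium_volume = c(781.8, 576.6, 100, 2500),
               depth = c(7.4, 3.1, 0, 14),
               sizing_target = 1.05),
    BAV0 = list(annulus_dmax = c(27.4, 3.5, 22, 34),
                annulus_dmin = c(21.7, 3.5, 17, 28),
                calcium_volume = c(1210.7, 778.0, 100, 2500),
                depth = c(6.2, 3.3, 0, 14),
                sizing_target = 0.98),
    BAV1 = list(annulus_dmax = c(29.6, 3.0, 22, 34),
                annulus_dmin = c(22.7, 3.4, 17, 28),
                calcium_volume = c(1213.5, 676.6, 100, 2500),
                depth = c(6.1, 4.2, 0, 14),
                sizing_target = 0.98))
}

#' Specification of a synthetic TAVR cohort
#'
#' @param n_tav,n_bav0,n_bav1 patient counts per valve morphology.
#' @param seed integer master seed; the whole cohort (covariates, calcium
#'   layouts, orientations) is a deterministic function of it.
#' @param covariates optional list overriding [default_covariates()]:
#'   per-morphology entries with `c(mean, sd, lower, upper)` vectors for
#'   `annulus_dmax`, `annulus_dmin`, `calcium_volume`, `depth`, plus a
#'   scalar `sizing_target` (minimum device-size / perimeter-derived
#'   diameter ratio used for size selection).
#' @param mesh_resolution passed to [root_params()].
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tav = 17, n_bav0 = 11, n_bav1 = 15, seed = 1,
                        covariates = default_covariates(),
                        mesh_resolution = c(96L, 60L)) {
  if (any(c(n_tav, n_bav0, n_bav1) < 0)) stop("counts must be >= 0")
  for (m in names(covariates)) {
    for (v in c("annulus_dmax", "annulus_dmin", "calcium_volume", "depth")) {
      cv <- covariates[[m]][[v]]
      if (cv[2] < 0) stop("SD must be >= 0 for ", m, "/", v)
      if (cv[3] >= cv[4]) stop("infeasible bounds for ", m, "/", v)
    }
  }
  structure(list(n_tav = n_tav, n_bav0 = n_bav0, n_bav1 = n_bav1,
                 seed = as.integer(seed), covariates = covariates,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "cohort_spec")
}

## Smallest available device size achieving the sizing target; falls back to
## the largest size for very large annuli.
select_device_size <- function(perimeter_diam, target) {
  ok <- DEVICE_SIZES >= target * perimeter_diam
  if (any(ok)) DEVICE_SIZES[which(ok)[1]] else DEVICE_SIZES[length(DEVICE_SIZES)]
}

## Random calcium layout for one patient: 2-5 deposits centred on leaflet
## bellies (plus the raphe for BAV1), volumes split by random proportions.
sample_calcium_layout <- function(volume, morphology, commissure_height,
                                  raphe_height_fraction) {
  layout <- root_layout(morphology)
  comms <- layout$commissures
  w <- pi / length(comms)
  nadirs <- wrap_angle(comms + w)
  n_dep <- min(max(2L, ceiling(volume / 500)), 5L)
  props <- stats::runif(n_dep, 0.5, 1.5)
  vols <- volume * props / sum(props)
  ## spread deposits over distinct leaflets (cycling when there are more
  ## deposits than leaflets) so nodules do not pile on one cusp
  nadir_seq <- rep(sample(nadirs), length.out = n_dep)
  deps <- vector("list", n_dep)
  for (k in seq_len(n_dep)) {
    if (morphology == "BAV1" && k == 1L) {
      ## raphe deposit on the fused commissure ridge
      ctr_a <- layout$fused
      ctr_h <- stats::runif(1, 0.25, 0.5) * raphe_height_fraction *
        commissure_height + 0.15 * commissure_height
    } else {
      ctr_a <- nadir_seq[k] + stats::runif(1, -0.3, 0.3) * w
      ctr_h <- stats::runif(1, 0.35, 0.7) * commissure_height
    }
    deps[[k]] <- calcium_deposit(
      center_angle = ctr_a, center_height = ctr_h,
      extent_angle = stats::runif(1, 0.8, 1.2),
      extent_height = stats::runif(1, 7, 11),
      volume = vols[k], protrusion = 5)
  }
  deps
}

#' Sample a seeded synthetic cohort
#'
#' Draws per-patient covariates from the per-morphology truncated-normal
#' distributions in `spec`, selects the device size as the smallest of
#' 23/26/29/32 mm reaching the configured sizing target, and builds the
#' corresponding [root_params()] (including a random calcium layout and,
#' for TAV, a random annular orientation).
#'
#' @param spec a [cohort_spec()].
#' @return list with `table` (one data.frame row per patient: patient_id,
#'   morphology, annulus_dmax, annulus_dmin, perimeter_diam, area_diam,
#'   calcium_volume, device_size, sizing_index, depth) and `params` (list of
#'   `root_params`, same order).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  morphs <- c(rep("TAV", spec$n_tav), rep("BAV0", spec$n_bav0),
              rep("BAV1", spec$n_bav1))
  n <- length(morphs)
  rows <- vector("list", n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    m <- morphs[i]
    cv <- spec$covariates[[m]]
    dmax <- rtruncnorm(1, cv$annulus_dmax[1], cv$annulus_dmax[2],
                       cv$annulus_dmax[3], cv$annulus_dmax[4])
    dmin <- rtruncnorm(1, cv$annulus_dmin[1], cv$annulus_dmin[2],
                       cv$annulus_dmin[3], cv$annulus_dmin[4])
    dmin <- min(dmin, dmax - 2)              # keep a physiologic ellipse
    dmin <- max(dmin, cv$annulus_dmin[3])
    calc <- rtruncnorm(1, cv$calcium_volume[1], cv$calcium_volume[2],
                       cv$calcium_volume[3], cv$calcium_volume[4])
    depth <- rtruncnorm(1, cv$depth[1], cv$depth[2], cv$depth[3], cv$depth[4])
    a <- dmax / 2; b <- dmin / 2
    pd <- ellipse_perimeter(a, b) / pi
    ad <- 2 * sqrt(a * b)                    # 2*sqrt(pi*a*b/pi)
    size <- select_device_size(pd, cv$sizing_target)
    orient <- if (m == "TAV") stats::runif(1, 0, 2 * pi / 3) else 0
    ch <- 0.7 * dmax                          # commissure height scales with root
    deposits <- sample_calcium_layout(calc, m, ch, 0.6)
    params[[i]] <- root_params(
      morphology = m, annulus_dmax = dmax, annulus_dmin = dmin,
      lvot_height = 12, sinus_radius_factor = 1.25,
      commissure_height = ch, stj_height = ch + 4, ascending_height = 14,
      raphe_height_fraction = 0.6, calcium_deposits = deposits,
      mesh_resolution = spec$mesh_resolution,
      ellipse_axis_angle = orient)
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i), morphology = m,
      annulus_dmax = dmax, annulus_dmin = dmin,
      perimeter_diam = pd, area_diam = ad,
      calcium_volume = calc, device_size = size,
      sizing_index = size / pd, depth = depth,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), params = params)
}

#' Write / read a cohort covariate table as CSV
#' @param cohort result of [sample_cohort()] (or its `table`).
#' @param path output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  tab <- if (is.data.frame(cohort)) cohort else cohort$table
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
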