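## End-to-end orchestration: synthetic cohort -> per-patient deployment ->
## sealing analysis -> frame metrics -> cohort statistics, with CSV outputs
## and a reproducibility manifest.

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()].
#' @param materials named list of [tissue_material()] (see
#'   [default_materials()]).
#' @param contact a [contact_params()].
#' @param sealing_threshold apposition threshold (mm, default 1.0).
#' @param pvl_thresholds surrogate grade thresholds in percent (t1, t2).
#' @param level_fractions a [level_specs()] vector.
#' @param crimp_diameter crimped delivery diameter (mm).
#' @param out_dir output directory for CSV artifacts (NULL = no files).
#' @param seed master seed for all per-patient random streams.
#' @param verbose print per-patient progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            materials = default_materials(),
                            contact = contact_params(),
                            sealing_threshold = 1.0,
                            pvl_thresholds = c(10, 25),
                            level_fractions = level_specs(),
                            crimp_diameter = 8,
                            out_dir = NULL, seed = 1, verbose = FALSE) {
  structure(list(cohort = cohort, materials = materials, contact = contact,
                 sealing_threshold = sealing_threshold,
                 pvl_thresholds = pvl_thresholds,
                 level_fractions = level_fractions,
                 crimp_diameter = crimp_diameter,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

#' Simulate a single patient
#'
#' Builds the root and frame, crimps, deploys at the patient's implantation
#' depth, and runs the sealing analysis and frame measurements.
#'
#' @param params a [root_params()].
#' @param covariates one row of the cohort table (needs `device_size` and
#'   `depth`).
#' @param config a [pipeline_config()].
#' @return list: `state`, `records`, `summary`, `grade`, `metrics`.
#' @export
simulate_patient <- function(params, covariates, config = pipeline_config()) {
  root <- build_root(params)
  fp <- frame_params(size_label = covariates$device_size)
  frame <- crimp(build_frame(fp), config$crimp_diameter)
  state <- match_depth(frame, root, covariates$depth,
                       contact = config$contact,
                       materials = config$materials)
  records <- sealing_records(state, threshold = config$sealing_threshold,
                             max_ray_length = config$contact$max_ray_length)
  summary <- summarize_sealing(records)
  grade <- pvl_surrogate(summary, config$pvl_thresholds)
  metrics <- measure_frame_levels(state$frame, config$level_fractions)
  list(state = state, records = records, summary = summary, grade = grade,
       metrics = metrics)
}

## Flatten a sealing summary into one row of cohort outputs.
sealing_row <- function(summary) {
  br <- summary$by_region
  g <- function(reg, col) br[br$region == reg, col]
  data.frame(
    lvot_apposed = g("LVOT", "apposed_area"),
    lvot_malapposed = g("LVOT", "malapposed_area"),
    triangles_apposed = g("INTERLEAFLET_TRIANGLE", "apposed_area"),
    triangles_malapposed = g("INTERLEAFLET_TRIANGLE", "malapposed_area"),
    leaflet_apposed = g("LEAFLET", "apposed_area"),
    leaflet_malapposed = g("LEAFLET", "malapposed_area"),
    malapposition_total_pct = summary$malapposition_total_pct,
    malapposition_lvot_pct = g("LVOT", "malapposition_pct"),
    malapposition_triangles_pct = g("INTERLEAFLET_TRIANGLE",
                                    "malapposition_pct"),
    malapposition_leaflet_pct = g("LEAFLET", "malapposition_pct"),
    apposition_total_pct = summary$apposition_total_pct,
    total_skirt_area = summary$total_skirt_area)
}

#' Run the full analysis pipeline
#'
#' Samples the cohort, simulates every patient (failures are isolated and
#' counted, not fatal), and aggregates the cohort table, the grouped
#' sealing-summary table, the PVL-grade breakdown, the frame
#' predicted-vs-observed comparison, and the univariate + stepwise
#' regression for malapposition in the interleaflet triangles.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `cohort` (per-patient table with
#'   sealing outputs and surrogate PVL grade), `group_table`,
#'   `grade_breakdown`, `frame_comparison`, `screen`, `stepwise`,
#'   `failures`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- sample_cohort(config$cohort)
  n <- nrow(cohort$table)
  rows <- vector("list", n)
  metrics_all <- vector("list", n)
  grades <- rep(NA_character_, n)
  failures <- character(0)
  for (i in seq_len(n)) {
    if (config$verbose) message("patient ", i, "/", n)
    set.seed(derive_seed(config$seed, i))
    res <- try(simulate_patient(cohort$params[[i]], cohort$table[i, ],
                                config), silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, paste0(cohort$table$patient_id[i], ": ",
                                     attr(res, "condition")$message))
      next
    }
    rows[[i]] <- sealing_row(res$summary)
    metrics_all[[i]] <- res$metrics
    grades[i] <- as.character(res$grade)
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("all patients failed: ", paste(failures,
                                                    collapse = "; "))
  tab <- cbind(cohort$table[ok, , drop = FALSE], do.call(rbind, rows[ok]))
  tab$pvl_grade <- grades[ok]
  tab$bav <- as.integer(tab$morphology != "TAV")
  rownames(tab) <- NULL
  ## grouped sealing table (published table shape)
  seal_vars <- c("lvot_apposed", "lvot_malapposed", "triangles_apposed",
                 "triangles_malapposed", "leaflet_apposed",
                 "leaflet_malapposed", "malapposition_total_pct",
                 "malapposition_lvot_pct", "malapposition_triangles_pct",
                 "malapposition_leaflet_pct", "apposition_total_pct")
  group_table <- if (length(unique(tab$morphology)) > 1 &&
                       sum(tab$bav == 0) >= 2 && sum(tab$bav == 1) >= 2)
    group_summary(tab, continuous = seal_vars) else NULL
  ## PVL-grade vs malapposition breakdown
  grade_breakdown <- do.call(rbind, lapply(split(tab, tab$pvl_grade),
    function(g) data.frame(grade = g$pvl_grade[1], n = nrow(g),
                           mean_malapposition = mean(g$malapposition_total_pct),
                           sd_malapposition = stats::sd(g$malapposition_total_pct))))
  rownames(grade_breakdown) <- NULL
  ## frame predicted-vs-observed comparison on synthetic "post-op" data
  predicted <- do.call(rbind, metrics_all[ok])
  observed <- perturb_measurements(predicted, seed = config$seed + 1L)
  frame_comparison <- compare_frames(predicted, observed)
  ## association with triangle malapposition: screen then stepwise
  candidates <- c("bav", "sizing_index", "calcium_volume", "depth",
                  "area_diam", "annulus_dmax")
  screen <- univariate_screen(tab, "malapposition_triangles_pct", candidates)
  retained <- screen$candidate[screen$retained]
  stepwise <- if (length(retained) > 0)
    stepwise_lm(tab, "malapposition_triangles_pct", retained) else NULL
  result <- structure(list(cohort = tab, group_table = group_table,
                           grade_breakdown = grade_breakdown,
                           frame_comparison = frame_comparison,
                           screen = screen, stepwise = stepwise,
                           failures = failures, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config$out_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$cohort), "patients analysed,",
      length(x$failures), "failures\n")
  means <- tapply(x$cohort$malapposition_total_pct,
                  x$cohort$morphology != "TAV", mean)
  cat("  total skirt malapposition: TAV",
      round(means[["FALSE"]], 1), "% vs BAV", round(means[["TRUE"]], 1),
      "%\n")
  invisible(x)
}

## Write CSV artifacts and return a manifest with md5 checksums.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(out_dir, "cohort.csv"),
             group_table = file.path(out_dir, "group_table.csv"),
             grade_breakdown = file.path(out_dir, "grade_breakdown.csv"),
             frame_comparison = file.path(out_dir, "frame_comparison.csv"),
             screen = file.path(out_dir, "univariate_screen.csv"))
  utils::write.csv(result$cohort, paths["cohort"], row.names = FALSE)
  if (!is.null(result$group_table))
    utils::write.csv(result$group_table, paths["group_table"],
                     row.names = FALSE)
  utils::write.csv(result$grade_breakdown, paths["grade_breakdown"],
                   row.names = FALSE)
  utils::write.csv(result$frame_comparison, paths["frame_comparison"],
                   row.names = FALSE)
  utils::write.csv(result$screen, paths["screen"], row.names = FALSE)
  existing <- paths[file.exists(paths)]
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config_as_list(result$config), cfg_file,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   checksums = as.list(tools::md5sum(existing)),
                   seed = result$config$seed,
                   version = as.character(utils::packageVersion("tavrseal")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

## Plain-list view of a config (for serialisation / hashing): strips S3
## classes recursively, including data.frames (kept as column lists).
config_as_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x)   # keep names through YAML
    else unclass(x)
  }
  strip(config)
}

#' Write / read a pipeline configuration as YAML
#'
#' The YAML round trip is lossless for all numeric/character fields; class
#' structure is rebuilt on read.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) / a `pipeline_config` (read).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cv <- raw$cohort$covariates
  cv <- lapply(cv, function(m) {
    m[names(m) != "sizing_target"] <- lapply(m[names(m) != "sizing_target"],
                                             unlist)
    m$sizing_target <- as.numeric(m$sizing_target)
    m
  })
  mats <- lapply(raw$materials, function(m)
    tissue_material(m$elastic_modulus, m$thickness, m$yield_stress))
  pipeline_config(
    cohort = cohort_spec(raw$cohort$n_tav, raw$cohort$n_bav0,
                         raw$cohort$n_bav1, raw$cohort$seed, cv,
                         unlist(raw$cohort$mesh_resolution)),
    materials = mats,
    contact = contact_params(raw$contact$friction_coefficient,
                             raw$contact$penalty_exponent,
                             raw$contact$max_ray_length,
                             raw$contact$release_schedule,
                             raw$contact$residual_tol,
                             raw$contact$max_iterations,
                             raw$contact$damping),
    sealing_threshold = raw$sealing_threshold,
    pvl_thresholds = unlist(raw$pvl_thresholds),
    level_fractions = level_specs(unlist(raw$level_fractions)),
    crimp_diameter = raw$crimp_diameter,
    out_dir = raw$out_dir, seed = raw$seed, verbose = isTRUE(raw$verbose))
}
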