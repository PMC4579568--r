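PARTICLE_COLUMNS <- c("particle_id", "mt_id", "axial_x_nm", "ring_height_nm",
                      "n_rings_visible", "pixel_sum", "class_label")
PARTICLE_NUMERIC <- c("axial_x_nm", "ring_height_nm", "pixel_sum")
RUN_COLUMNS <- c("molecule_id", "run_length_nm", "duration_s",
                 "velocity_nm_per_s")

#' Read a particle table (TSV)
#'
#' Tab-separated, UTF-8, '.' decimal, with a header naming at least the
#' mandatory columns `particle_id`, `mt_id`, `axial_x_nm`, `ring_height_nm`,
#' `n_rings_visible`, `pixel_sum`, `class_label`. Unknown columns and the
#' row order are preserved. A non-numeric coordinate is reported with its
#' line number.
#'
#' @param path File path.
#' @return Data frame of particle records.
#' @export
read_particle_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE)
  missing_cols <- setdiff(PARTICLE_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c(PARTICLE_NUMERIC, "n_rings_visible")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0)
      stop(sprintf("row error: non-numeric value '%s' in column '%s' at line %d",
                   raw[[col]][bad[1]], col, bad[1] + 1L), call. = FALSE)
    raw[[col]] <- if (col == "n_rings_visible") as.integer(vals) else vals
  }
  raw
}

#' Write a particle table (TSV)
#' @param particles Data frame of particle records.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(particles, path) {
  utils::write.table(particles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a single-molecule run table (TSV)
#'
#' Columns: `molecule_id`, `run_length_nm`, `duration_s`,
#' `velocity_nm_per_s`.
#'
#' @param path File path.
#' @return Data frame of run records.
#' @export
read_run_table <- function(path) {
  runs <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  missing_cols <- setdiff(RUN_COLUMNS, names(runs))
  if (length(missing_cols) > 0)
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  runs
}

#' Write a single-molecule run table (TSV)
#' @param runs Data frame of run records.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_run_table <- function(runs, path) {
  utils::write.table(runs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a full pipeline configuration
#'
#' @param lattice A [lattice_params()] object.
#' @param geometry A [motor_geometry()] object.
#' @param mechanics A [mechanical_params()] object.
#' @param generation A [gen_config()] object.
#' @param kinetics List of kinetics options (`step_sizes`, `criterion`,
#'   `n_runs`).
#' @param mode Ring-separation reporting convention.
#' @param window Running-average window.
#' @param exclusion_nm Isolation clearance (nm).
#' @param seed Global seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(lattice = lattice_params(),
                            geometry = motor_geometry(),
                            mechanics = mechanical_params(),
                            generation = gen_config(),
                            kinetics = list(step_sizes = c(16.6, 8.3, 4.15),
                                            criterion = "median",
                                            n_runs = 2000L),
                            mode = "as_published", window = 100L,
                            exclusion_nm = 40, seed = 1L) {
  structure(list(lattice = lattice, geometry = geometry,
                 mechanics = mechanics, generation = generation,
                 kinetics = kinetics, mode = mode, window = as.integer(window),
                 exclusion_nm = exclusion_nm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()] object.
#' @param path File path.
#' @return `path` invisibly (write); a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sw <- unlist(y$generation$separation_weights)
  pipeline_config(
    lattice = do.call(lattice_params, y$lattice),
    geometry = do.call(motor_geometry, y$geometry),
    mechanics = do.call(mechanical_params,
                        y$mechanics[!vapply(y$mechanics, is.null, TRUE)]),
    generation = gen_config(n_dimers = y$generation$n_dimers,
                            seed = y$generation$seed,
                            separation_weights = sw,
                            measurement_noise_sd = y$generation$measurement_noise_sd,
                            crowding_density = y$generation$crowding_density),
    kinetics = y$kinetics, mode = y$mode, window = y$window,
    exclusion_nm = y$exclusion_nm, seed = y$seed)
}

#' Run the full pipeline: simulate, measure, mechanics, kinetics
#'
#' Executes the stages in order on synthetic data and writes each stage's
#' table or report under `out_dir`, together with a JSON manifest recording
#' the package version, seed and parameters. Stage failures abort with the
#' stage name.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "measure", "mechanics", "kinetics")`. Later stages read
#'   the tables earlier stages wrote, so a subset can rerun downstream
#'   stages on saved tables.
#' @return List with the mechanics and kinetics reports (invisibly).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "measure", "mechanics",
                                    "kinetics")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  particles_path <- file.path(out_dir, "particles.tsv")
  dimers_path <- file.path(out_dir, "dimers.tsv")
  sup_path <- file.path(out_dir, "superposed.tsv")

  if ("simulate" %in% stages) run_stage("simulate", {
    particles <- generate_particles(config$generation, config$mechanics,
                                    config$geometry, config$lattice)
    write_particle_table(particles, particles_path)
  })
  if ("measure" %in% stages) run_stage("measure", {
    if (!file.exists(particles_path))
      stop("particle table not found (run the simulate stage first): ",
           particles_path)
    particles <- read_particle_table(particles_path)
    measured <- measure_particles(particles, config$geometry)
    offs <- measured[measured$class_label == "offset", ]
    offs$pair_id <- as.integer(offs$pair_id)
    # keep only pairs whose two motors both survived measurement
    complete <- names(which(table(offs$pair_id) == 2L))
    offs <- offs[offs$pair_id %in% as.integer(complete), ]
    dimers <- dimer_table(offs)
    utils::write.table(dimers, dimers_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sup <- measured[measured$class_label == "superposed",
                    c("particle_id", "theta_deg")]
    utils::write.table(sup, sup_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  mech_rep <- NULL
  if ("mechanics" %in% stages) mech_rep <- run_stage("mechanics", {
    if (!file.exists(dimers_path))
      stop("dimer table not found (run the measure stage first): ",
           dimers_path)
    dimers <- utils::read.delim(dimers_path)
    sup <- utils::read.delim(sup_path)
    rep <- mechanics_report(dimers, sup$theta_deg, config$geometry,
                            config$mechanics$thermal_energy,
                            mode = config$mode, window = config$window)
    writeLines(jsonlite::toJSON(report_numbers(rep), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
               file.path(out_dir, "mechanics.json"))
    rep
  })
  kin_rep <- NULL
  if ("kinetics" %in% stages) kin_rep <- run_stage("kinetics", {
    r_true <- duty_ratio(steps_per_run(600, 8.3))
    runs <- simulate_runs(r_true, 8.3, config$kinetics$n_runs,
                          config$seed + 7L)
    rep <- kinetics_report(runs, config$kinetics$step_sizes,
                           config$kinetics$criterion)
    writeLines(jsonlite::toJSON(report_numbers(rep), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
               file.path(out_dir, "kinetics.json"))
    rep
  })
  manifest <- list(
    package = "dyneinflex",
    version = as.character(utils::packageVersion("dyneinflex")),
    seed = config$seed, stages = stages,
    parameters = lapply(unclass(config), function(x)
      if (is.list(x)) unclass(x) else x))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(list(mechanics = mech_rep, kinetics = kin_rep))
}

#' Flatten a mechanics or kinetics report into plain named numbers
#'
#' Produces a nested list of bare numbers suitable for JSON serialization.
#'
#' @param rep A `mechanics_report` or `kinetics_report`.
#' @return A named list of numbers and short strings.
#' @export
report_numbers <- function(rep) {
  if (inherits(rep, "mechanics_report")) {
    list(
      sigma_deg = list(leading = rep$leading$sigma_deg,
                       trailing = rep$trailing$sigma_deg,
                       superposed = rep$superposed$sigma_deg),
      kappa_pN_nm_rad2 = list(leading = rep$leading$kappa,
                              trailing = rep$trailing$kappa,
                              superposed = rep$superposed$kappa),
      cantilever_pN_nm = list(leading = rep$leading$cantilever_k,
                              trailing = rep$trailing$cantilever_k,
                              superposed = rep$superposed$cantilever_k),
      regression = list(
        leading = list(slope = rep$fit_leading$slope,
                       intercept = rep$fit_leading$intercept),
        trailing = list(slope = rep$fit_trailing$slope,
                        intercept = rep$fit_trailing$intercept)),
      pairwise_slope_deg_per_nm = rep$pairwise_slope,
      tension_per_nm = list(leading = rep$tension_per_nm_leading,
                            trailing = rep$tension_per_nm_trailing,
                            mean = rep$tension_per_nm_mean),
      tensions_at_pN = as.list(rep$tensions_at),
      ring_separations_nm = as.list(rep$ring_separations),
      tether_stiffness_pN_nm = rep$tether_stiffness,
      mode = rep$mode, n = rep$n)
  } else if (inherits(rep, "kinetics_report")) {
    list(run_mean_nm = rep$run_fit$mean,
         detection_floor_nm = rep$run_fit$detection_floor,
         step_sizes_nm = rep$step_sizes,
         steps_per_run = rep$steps_per_run,
         duty_ratios = rep$duty_ratios,
         criterion = rep$criterion, n = rep$run_fit$n)
  } else unclass(rep)
}
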