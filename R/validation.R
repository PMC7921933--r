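# Measured and published-model bioyield values per storage day x probe
# velocity, shipped verbatim (also as inst/extdata/table_bioyield_validation.csv).
# The "level" column indexes velocity within each day. Forces in N,
# deformations in mm, errors in percent.
.bioyield_table <- data.frame(
  day = rep(c(0, 4, 7), each = 3),
  velocity = rep(c(1.5, 2, 2.5), 3),
  level = rep(1:3, 3),
  force_measured = c(17.81, 17.87, 18.36, 14.87, 15.31, 16.42, 13.20, 13.43, 13.55),
  force_measured_se = c(0.64, 2.22, 0.08, 0.87, 2.11, 0.91, 2.13, 0.89, 1.33),
  force_simulated = c(17.30, 17.35, 17.57, 14.76, 15.81, 16.81, 11.29, 12.22, 14.29),
  force_simulated_se = c(0.091, 0.11, 0.14, 0.27, 0.19, 0.22, 0.19, 0.20, 0.20),
  force_error = c(2.86, 2.91, 4.30, 0.74, 3.26, 2.37, 14.46, 9.00, 5.46),
  deformation_measured = c(1.5, 1.67, 1.8, 1.21, 1.35, 1.45, 1.22, 1.38, 1.43),
  deformation_measured_se = c(0.29, 0.27, 0.12, 0.07, 0.09, 0.17, 0.16, 0.05, 0.44),
  deformation_simulated = c(2, 2.15, 2.2, 2, 2.1, 2.35, 1.8, 1.85, 1.9),
  deformation_simulated_se = c(0.15, 0.16, 0.15, 0.20, 0.21, 0.29, 0.15, 0.18, 0.16),
  deformation_error = c(33.33, 28.74, 22.22, 65.28, 55.55, 62.06, 47.54, 34.05, 32.86))

#' Measured bioyield validation table
#'
#' Measured (and previously published model) bioyield force and deformation
#' per storage day (0, 4, 7) and probe velocity (1.5, 2, 2.5 mm/s), with
#' standard errors and relative errors. Used as the calibration and
#' validation reference; never consumed by solver-core unit tests.
#'
#' @return Data frame of 9 conditions.
#' @export
bioyield_table <- function() .bioyield_table

#' Calibration specification
#'
#' Bounded coordinate-descent search over material parameters (and
#' optionally the erosion limit) against measured bioyield forces. Grids for
#' tissue parameters must lie inside the measured min-max levels
#' (\code{\link{material_levels}}).
#'
#' @param ranges Named list of numeric grid vectors. Names are
#'   \code{"skin.<field>"}, \code{"flesh.<field>"} with field one of E,
#'   sigma_y, Et, nu, rho, or \code{"epsp_max"}.
#' @param budget Maximum number of simulator evaluations. Default 40.
#' @return Object of class \code{calibration_spec}.
#' @export
calibration_spec <- function(ranges, budget = 40) {
  if (!is.list(ranges) || length(ranges) == 0 || is.null(names(ranges)))
    stop("calibration_spec: ranges must be a non-empty named list", call. = FALSE)
  for (nm in names(ranges)) {
    g <- ranges[[nm]]
    if (length(g) == 0 || any(!is.finite(g)))
      stop("calibration_spec: empty or non-finite grid for ", nm, call. = FALSE)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] %in% c("skin", "flesh")) {
      lv <- .material_levels[.material_levels$tissue == parts[1], ]
      if (!parts[2] %in% names(lv))
        stop("calibration_spec: unknown material field in ", nm, call. = FALSE)
      lo <- min(lv[[parts[2]]]); hi <- max(lv[[parts[2]]])
      if (any(g < lo - 1e-12) || any(g > hi + 1e-12))
        stop("calibration_spec: grid for ", nm,
             " leaves the measured min-max range [", lo, ", ", hi, "]",
             call. = FALSE)
    } else if (nm != "epsp_max") {
      stop("calibration_spec: unknown parameter ", nm, call. = FALSE)
    }
  }
  if (budget < 1) stop("calibration_spec: budget must be >= 1", call. = FALSE)
  structure(list(ranges = ranges, budget = budget), class = "calibration_spec")
}

#' Calibrate model parameters against measured bioyield forces
#'
#' Deterministic coordinate descent on the grids of a
#' \code{\link{calibration_spec}}: coordinates are swept in the order given,
#' each set to the grid value minimising the mean relative error of the
#' runner's output against the targets, repeating until a full sweep changes
#' nothing or the evaluation budget is exhausted. Evaluations are memoised.
#'
#' @param spec A \code{\link{calibration_spec}}.
#' @param targets Measured bioyield force(s) (N) the runner output is
#'   compared against.
#' @param runner Function taking a named list of parameter values (the
#'   \code{ranges} names) and returning the simulated bioyield force (N),
#'   or a vector matched against \code{targets} elementwise.
#' @param start Optional named list of starting values (snapped to the
#'   nearest grid point); defaults to each grid's midpoint.
#' @return List with \code{params} (named list), \code{objective} (mean
#'   relative error, percent), \code{evals}, \code{budget_exhausted}.
#' @export
calibrate <- function(spec, targets, runner, start = NULL) {
  stopifnot(inherits(spec, "calibration_spec"))
  if (length(targets) < 1 || any(!is.finite(targets)) || any(targets == 0))
    stop("calibrate: targets must be finite and nonzero", call. = FALSE)
  nms <- names(spec$ranges)
  idx <- vapply(nms, function(nm) {
    g <- spec$ranges[[nm]]
    if (!is.null(start[[nm]])) which.min(abs(g - start[[nm]]))
    else as.integer(ceiling(length(g) / 2))
  }, integer(1))
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  exhausted <- FALSE
  objective <- function(ix) {
    key <- paste(ix, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (evals >= spec$budget) { exhausted <<- TRUE; return(NA_real_) }
    evals <<- evals + 1L
    p <- stats::setNames(lapply(seq_along(nms),
                                function(k) spec$ranges[[nms[k]]][ix[k]]), nms)
    val <- try(runner(p), silent = TRUE)
    obj <- if (inherits(val, "try-error") || any(!is.finite(val))) Inf
           else mean(relative_error(targets, val))
    cache[[key]] <- obj
    obj
  }
  best <- objective(idx)
  repeat {
    changed <- FALSE
    for (k in seq_along(nms)) {
      ng <- length(spec$ranges[[nms[k]]])
      if (ng == 1) next
      objs <- vapply(seq_len(ng), function(j) {
        ix <- idx; ix[k] <- j; objective(ix)
      }, numeric(1))
      if (all(is.na(objs))) next
      jbest <- which.min(ifelse(is.na(objs), Inf, objs))
      if (jbest != idx[k] && is.finite(objs[jbest]) &&
          objs[jbest] < best - 1e-12) {
        idx[k] <- jbest
        best <- objs[jbest]
        changed <- TRUE
      }
      if (exhausted) break
    }
    if (!changed || exhausted) break
  }
  params <- stats::setNames(lapply(seq_along(nms),
                                   function(k) spec$ranges[[nms[k]]][idx[k]]), nms)
  if (exhausted)
    warning("calibrate: evaluation budget exhausted; returning best so far",
            call. = FALSE)
  list(params = params, objective = best, evals = evals,
       budget_exhausted = exhausted)
}

# apply "skin.field"/"flesh.field" overrides to a materials list
.apply_overrides <- function(materials, params) {
  cfg <- list(epsp_max = NULL)
  for (nm in names(params)) {
    if (nm == "epsp_max") { cfg$epsp_max <- params[[nm]]; next }
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    m <- materials[[parts[1]]]
    fields <- list(E = m$E, sigma_y = m$sigma_y, Et = m$Et, nu = m$nu, rho = m$rho)
    fields[[parts[2]]] <- params[[nm]]
    materials[[parts[1]]] <- do.call(material_params, fields)
  }
  list(materials = materials, epsp_max = cfg$epsp_max)
}

#' Default validation-study configuration
#'
#' Settings for the full storage-day by velocity validation study: domain
#' and mesh resolution, probe velocities, solver controls, the default
#' day-to-level mapping (day 0 at the maximum property level, day 4 average,
#' day 7 minimum, reflecting the measured decline of all properties over
#' storage), and the calibration search.
#'
#' @param target_h Validation-run element size under the probe (mm).
#' @param calibration_target_h Element size used during calibration sweeps.
#' @param dd Validation-run depth increment (mm).
#' @param calibration_dd Depth increment during calibration sweeps.
#' @param max_insertion Simulated insertion depth (mm); must comfortably
#'   exceed the bioyield deformation.
#' @param epsp_max Erosion plastic-strain limit (calibrated when
#'   \code{"epsp_max"} appears in the calibration ranges).
#' @param calibrate Logical: calibrate per-day parameters against the
#'   measured forces (TRUE) or run the mapped levels as-is.
#' @param budget Calibration evaluation budget per day.
#' @return Nested configuration list.
#' @export
default_config <- function(target_h = 0.5, calibration_target_h = 0.5,
                           dd = 0.02, calibration_dd = 0.05,
                           max_insertion = 3, epsp_max = 0.5,
                           calibrate = TRUE, budget = 60) {
  list(
    domain = list(radius = 15, depth = 20, skin_thickness = 1, probe_radius = 1),
    mesh = list(target_h = target_h, refinement_ratio = 4),
    calibration_mesh = list(target_h = calibration_target_h, refinement_ratio = 4),
    probe = list(velocities = c(1.5, 2, 2.5), max_insertion = max_insertion),
    solver = list(mode = "quasi_static", epsp_max = epsp_max, dd = dd,
                  penalty_scale = 100),
    calibration = list(enabled = calibrate, budget = budget,
                       dd = calibration_dd, start = "avg",
                       ranges = list(
                         flesh.E = c(0.5, 1, 2, 3, 4),
                         skin.sigma_y = seq(0.5, 4, length.out = 8),
                         flesh.sigma_y = c(0.05, 0.5, 1, 1.4, 1.8),
                         skin.E = c(2, 4, 6, 10, 15))),
    days = list(`0` = "max", `4` = "avg", `7` = "min"))
}

#' Read a study configuration from YAML or JSON
#'
#' Fields present in the file override \code{\link{default_config}} entries
#' (shallow-merged per section).
#'
#' @param path Path to a .yaml/.yml or .json configuration file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(raw)) {
    if (is.list(raw[[sec]]) && is.list(cfg[[sec]])) {
      for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
    } else cfg[[sec]] <- raw[[sec]]
  }
  cfg
}

# one quasi-static run for given materials/epsp_max under a config
.run_condition <- function(config, materials, epsp_max, velocity,
                           mesh = NULL, dd = NULL, snapshot_depths = numeric(0)) {
  if (is.null(mesh)) {
    spec <- do.call(domain_spec, config$domain)
    mesh <- build_mesh(spec, config$mesh$target_h, config$mesh$refinement_ratio)
  }
  probe <- probe_spec(radius = config$domain$probe_radius, velocity = velocity,
                      max_insertion = config$probe$max_insertion)
  sc <- solver_config("quasi_static",
                      penalty_scale = config$solver$penalty_scale,
                      epsp_max = epsp_max,
                      dd = if (is.null(dd)) config$solver$dd else dd)
  solve_quasi_static(mesh, materials, probe, sc,
                     snapshot_depths = snapshot_depths)
}

#' Run the storage-day by velocity validation study
#'
#' For each storage day, assigns the mapped material level, optionally
#' calibrates the configured parameter ranges against that day's measured
#' bioyield forces (inverse analysis), then simulates the puncture and
#' compares simulated bioyield force and deformation with the measured
#' table via the relative-error statistic. The quasi-static model is
#' rate-independent, so one simulation per day covers all velocities of
#' that day (the time column alone differs).
#'
#' @param config Configuration list from \code{\link{default_config}} or
#'   \code{\link{read_config}}.
#' @param measured Measured reference table, default
#'   \code{\link{bioyield_table}()}. Must have columns day, velocity,
#'   force_measured, deformation_measured.
#' @param runner Optional replacement for the FE simulator: a function
#'   \code{(day, velocity, materials, epsp_max)} returning a
#'   \code{\link{force_deformation_curve}} or \code{simulation_result}.
#'   When supplied, one run per day x velocity condition is performed (the
#'   replacement need not be rate-independent).
#' @param verbose Print per-day progress.
#' @return Object of class \code{validation_report}: \code{records} (one row
#'   per day x velocity), \code{summary} (max/mean relative errors,
#'   calibration objectives), \code{calibrations}, and the day
#'   \code{results} (simulation outputs).
#' @export
run_validation <- function(config = default_config(),
                           measured = bioyield_table(), runner = NULL,
                           verbose = FALSE) {
  days <- sort(unique(measured$day))
  spec <- do.call(domain_spec, config$domain)
  mesh_val <- build_mesh(spec, config$mesh$target_h, config$mesh$refinement_ratio)
  mesh_cal <- build_mesh(spec, config$calibration_mesh$target_h,
                         config$calibration_mesh$refinement_ratio)
  records <- list()
  calibrations <- list()
  results <- list()
  for (d in days) {
    level <- config$days[[as.character(d)]]
    if (is.null(level)) level <- "avg"
    base <- list(skin = material_level_params("skin", level),
                 flesh = material_level_params("flesh", level))
    targets <- measured$force_measured[measured$day == d]
    vels <- measured$velocity[measured$day == d]
    params <- list()
    cal <- NULL
    if (isTRUE(config$calibration$enabled)) {
      cs <- calibration_spec(config$calibration$ranges,
                             budget = config$calibration$budget)
      cal_runner <- function(p) {
        ov <- .apply_overrides(base, p)
        em <- if (is.null(ov$epsp_max)) config$solver$epsp_max else ov$epsp_max
        sim <- .run_condition(config, ov$materials, em, velocity = vels[1],
                              mesh = mesh_cal, dd = config$calibration$dd)
        met <- detect_bioyield(sim$curve)
        # a parameter set that never ruptures within the insertion range
        # cannot reproduce the experiment, whatever force it reaches
        if (!met$rupture_detected) return(NA_real_)
        met$bioyield_force
      }
      start_level <- config$calibration$start
      if (is.null(start_level)) start_level <- "avg"
      start <- lapply(names(cs$ranges), function(nm) {
        parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
        if (length(parts) == 2) {
          m <- material_level_params(parts[1], start_level)
          list(E = m$E, sigma_y = m$sigma_y, Et = m$Et, nu = m$nu,
               rho = m$rho)[[parts[2]]]
        } else config$solver$epsp_max
      })
      names(start) <- names(cs$ranges)
      cal <- calibrate(cs, targets, cal_runner, start = start)
      params <- cal$params
      if (verbose)
        message(sprintf("day %s: calibrated (objective %.2f%%, %d evals)",
                        d, cal$objective, cal$evals))
    }
    ov <- .apply_overrides(base, params)
    em <- if (is.null(ov$epsp_max)) config$solver$epsp_max else ov$epsp_max
    calibrations[[as.character(d)]] <- cal
    dmeas <- measured$deformation_measured[measured$day == d]

    # the quasi-static FE model is rate-independent: one run covers the
    # day; a user-supplied runner is evaluated per velocity
    mets <- vector("list", length(vels))
    if (is.null(runner)) {
      sim <- try(.run_condition(config, ov$materials, em, velocity = vels[1],
                                mesh = mesh_val), silent = TRUE)
      if (!inherits(sim, "try-error")) {
        results[[as.character(d)]] <- sim
        met <- detect_bioyield(sim$curve)
        for (i in seq_along(vels)) mets[[i]] <- met
      }
    } else {
      for (i in seq_along(vels)) {
        sim <- try(runner(d, vels[i], ov$materials, em), silent = TRUE)
        if (inherits(sim, "try-error")) next
        if (inherits(sim, "simulation_result")) sim <- sim$curve
        mets[[i]] <- detect_bioyield(sim)
      }
    }
    for (i in seq_along(vels)) {
      met <- mets[[i]]
      records[[length(records) + 1]] <- if (is.null(met)) data.frame(
        day = d, velocity = vels[i], ok = FALSE, rupture_detected = NA,
        force_measured = targets[i], force_simulated = NA_real_,
        force_error = NA_real_,
        deformation_measured = dmeas[i],
        deformation_simulated = NA_real_, deformation_error = NA_real_)
      else data.frame(
        day = d, velocity = vels[i], ok = TRUE,
        rupture_detected = met$rupture_detected,
        force_measured = targets[i],
        force_simulated = met$bioyield_force,
        force_error = relative_error(targets[i], met$bioyield_force),
        deformation_measured = dmeas[i],
        deformation_simulated = met$bioyield_deformation,
        deformation_error = relative_error(dmeas[i], met$bioyield_deformation))
    }
  }
  records <- do.call(rbind, records)
  ok <- records$ok
  summary <- list(
    n_conditions = nrow(records),
    n_completed = sum(ok),
    max_force_error = if (any(ok)) max(records$force_error[ok]) else NA_real_,
    mean_force_error = if (any(ok)) mean(records$force_error[ok]) else NA_real_,
    max_deformation_error = if (any(ok)) max(records$deformation_error[ok]) else NA_real_,
    calibration_objectives = lapply(calibrations, function(c)
      if (is.null(c)) NULL else c$objective))
  structure(list(records = records, summary = summary,
                 calibrations = calibrations, results = results,
                 config = config),
            class = "validation_report")
}

#' @exportS3Method base::print
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation over %d conditions (%d completed)\n",
              x$summary$n_conditions, x$summary$n_completed))
  if (is.finite(x$summary$max_force_error))
    cat(sprintf("  bioyield force relative error: max %.2f%%, mean %.2f%%\n",
                x$summary$max_force_error, x$summary$mean_force_error))
  print(x$records[, c("day", "velocity", "force_measured", "force_simulated",
                      "force_error")], row.names = FALSE)
  invisible(x)
}

#' Write validation outputs to files
#'
#' Writes \code{validation.csv} (one row per condition) and
#' \code{summary.json}; with \code{plots = TRUE} also
#' \code{force_curves.pdf} with the simulated force-deformation overlays.
#' Output is byte-deterministic for identical inputs.
#'
#' @param report A \code{\link{run_validation}} result (or a list with
#'   \code{records} and \code{summary}).
#' @param out_dir Output directory, created if needed.
#' @param plots Also write force-curve overlays. Default FALSE.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, out_dir, plots = FALSE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("write_report: cannot create output directory ", out_dir, call. = FALSE)
  records <- report$records
  summary <- report$summary
  if (is.null(records) || nrow(records) == 0) {
    records <- data.frame(day = numeric(0), velocity = numeric(0))
    summary <- c(summary, list(no_data = TRUE))
  }
  csv <- file.path(out_dir, "validation.csv")
  utils::write.csv(records, csv, row.names = FALSE)
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(validation = csv, summary = js)
  if (plots && length(report$results)) {
    pdf_path <- file.path(out_dir, "force_curves.pdf")
    grDevices::pdf(pdf_path, width = 6, height = 4)
    on.exit(grDevices::dev.off())
    for (d in names(report$results)) {
      cv <- report$results[[d]]$curve
      graphics::plot(cv$depths, cv$forces, type = "l",
                     xlab = "insertion depth (mm)", ylab = "force (N)",
                     main = paste("storage day", d))
    }
    files <- c(files, plot = pdf_path)
  }
  invisible(files)
}
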