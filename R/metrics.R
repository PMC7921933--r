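#' Detect the bioyield point of a force-deformation curve
#'
#' The bioyield point is the first force peak at which tissue begins to
#' rupture: operationally, the first local maximum of the moving-average
#' smoothed force whose subsequent drop (before the force first re-exceeds
#' that maximum) exceeds \code{drop_fraction} times the maximum. The
#' reported force and deformation are the unsmoothed values at the raw-force
#' argmax within \code{smooth_window} samples of the detected smoothed peak,
#' so noise-free synthetic peaks are recovered exactly. If no qualifying
#' drop exists, \code{rupture_detected} is \code{FALSE} and the metrics are
#' taken at the global maximum.
#'
#' @param curve A \code{\link{force_deformation_curve}} with >= 10 samples.
#' @param smooth_window Moving-average window (samples), default 5.
#' @param drop_fraction Required post-peak drop as a fraction of the peak
#'   force, in (0, 1). Default 0.05.
#' @param fields Optional field summary (e.g. a simulation snapshot) whose
#'   \code{vm} entry supplies \code{peak_von_mises}.
#' @return Object of class \code{puncture_metrics}: \code{bioyield_force}
#'   (N), \code{bioyield_deformation} (mm), \code{bioyield_index},
#'   \code{rupture_detected}, \code{peak_von_mises} (MPa or NA).
#' @export
detect_bioyield <- function(curve, smooth_window = 5, drop_fraction = 0.05,
                            fields = NULL) {
  stopifnot(inherits(curve, "force_deformation_curve"))
  f <- curve$forces
  n <- length(f)
  if (n < 10)
    stop("insufficient-data: need at least 10 samples", call. = FALSE)
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("detect_bioyield: drop_fraction must lie in (0, 1)", call. = FALSE)
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2 == 0) w <- w + 1L
  fs <- as.numeric(stats::filter(f, rep(1 / w, w), sides = 2))
  na <- is.na(fs)
  fs[na] <- f[na]

  # local maxima of the smoothed force (plateaus count once, at their start)
  dfs <- diff(fs)
  is_max <- c(FALSE, dfs[-length(dfs)] > 0 & dfs[-1] <= 0, FALSE)
  cand <- which(is_max)
  pick <- NA_integer_
  for (i in cand) {
    peak <- fs[i]
    after <- fs[seq(i + 1L, n)]
    above <- which(after > peak)
    stopat <- if (length(above)) above[1] - 1L else length(after)
    if (stopat < 1L) next
    if (peak - min(after[seq_len(stopat)]) >= drop_fraction * peak) {
      pick <- i
      break
    }
  }
  rupture <- !is.na(pick)
  if (!rupture) pick <- which.max(f)
  lo <- max(1L, pick - w)
  hi <- min(n, pick + w)
  idx <- (lo:hi)[which.max(f[lo:hi])]

  pvm <- NA_real_
  if (!is.null(fields) && !is.null(fields$vm)) pvm <- max(fields$vm)
  structure(list(bioyield_force = f[idx],
                 bioyield_deformation = curve$depths[idx],
                 bioyield_index = idx,
                 rupture_detected = rupture,
                 peak_von_mises = pvm),
            class = "puncture_metrics")
}

#' @exportS3Method base::print
print.puncture_metrics <- function(x, ...) {
  cat(sprintf("Bioyield: F = %.4g N at d = %.4g mm (%s)\n",
              x$bioyield_force, x$bioyield_deformation,
              if (x$rupture_detected) "rupture detected" else "no qualifying drop"))
  if (is.finite(x$peak_von_mises))
    cat(sprintf("  peak von Mises stress %.4g MPa\n", x$peak_von_mises))
  invisible(x)
}

#' Relative error between measured and simulated values
#'
#' \code{|XE - XF| / XE * 100}, the validation statistic comparing an
#' experimental value \code{XE} with a simulated value \code{XF}.
#' Non-negative, zero iff the values agree, normalised by the measured
#' value only.
#'
#' @param XE Measured (experimental) reference value, nonzero. Vectorised.
#' @param XF Simulated value.
#' @return Relative error in percent.
#' @examples
#' relative_error(17.81, 17.30)  # 2.86
#' @export
relative_error <- function(XE, XF) {
  if (any(!is.finite(XE)) || any(!is.finite(XF)))
    stop("relative_error: values must be finite", call. = FALSE)
  if (any(XE == 0))
    stop("undefined-reference: measured value XE must be nonzero", call. = FALSE)
  abs(XE - XF) / abs(XE) * 100
}

#' Material-parameter sensitivity study
#'
#' Runs the puncture model over combinations of the measured property levels
#' (min/avg/max per tissue), extracts the bioyield force of each cell, and
#' reports the percent decrease from the all-max to the all-min combination,
#' \code{(F_max - F_min) / F_max * 100}. A failing cell is flagged and the
#' study continues.
#'
#' @param runner Function taking \code{(skin, flesh)}
#'   \code{\link{material_params}} and returning either a
#'   \code{simulation_result}, a \code{\link{force_deformation_curve}}, or a
#'   single numeric force (N).
#' @param levels Character vector of levels to cross, default
#'   \code{c("min", "avg", "max")} applied to both tissues jointly
#'   (skin and flesh at the same level), plus any extra combinations given
#'   in \code{combos}.
#' @param combos Optional data frame with columns \code{skin}, \code{flesh}
#'   naming levels for each run; overrides \code{levels}.
#' @param ... Passed to \code{\link{detect_bioyield}}.
#' @return List with \code{table} (data frame: skin, flesh, bioyield force,
#'   ok flag) and \code{percent_decrease} (all-max vs all-min; NA when
#'   either cell failed or all-max is absent).
#' @export
sensitivity_study <- function(runner, levels = c("min", "avg", "max"),
                              combos = NULL, ...) {
  if (is.null(combos))
    combos <- data.frame(skin = levels, flesh = levels,
                         stringsAsFactors = FALSE)
  forces <- rep(NA_real_, nrow(combos))
  ok <- rep(FALSE, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    res <- try({
      out <- runner(material_level_params("skin", combos$skin[i]),
                    material_level_params("flesh", combos$flesh[i]))
      if (inherits(out, "simulation_result")) out <- out$curve
      if (inherits(out, "force_deformation_curve"))
        out <- detect_bioyield(out, ...)$bioyield_force
      as.numeric(out)
    }, silent = TRUE)
    if (!inherits(res, "try-error") && is.finite(res)) {
      forces[i] <- res
      ok[i] <- TRUE
    }
  }
  tab <- cbind(combos, bioyield_force = forces, ok = ok)
  imax <- which(combos$skin == "max" & combos$flesh == "max")
  imin <- which(combos$skin == "min" & combos$flesh == "min")
  pdec <- NA_real_
  if (length(imax) == 1 && length(imin) == 1 && ok[imax] && ok[imin] &&
      forces[imax] != 0)
    pdec <- (forces[imax] - forces[imin]) / forces[imax] * 100
  list(table = tab, percent_decrease = pdec)
}

#' Quadratic no-intercept fit of a velocity effect
#'
#' Least-squares fit of \code{delta = a v^2 + b v} (no intercept) relating a
#' bioyield force or deformation difference to probe velocity, with the
#' coefficient of determination computed against the no-intercept model
#' (uncentered R^2).
#'
#' @param velocities Probe velocities (mm/s), length >= 3.
#' @param deltas Bioyield force (N) or deformation (mm) differences, same
#'   length. How the differences are paired is up to the caller.
#' @return Object of class \code{velocity_effect_fit} with \code{a},
#'   \code{b}, \code{r_squared} and \code{fitted}.
#' @export
fit_velocity_effect <- function(velocities, deltas) {
  if (length(velocities) < 3 || length(deltas) != length(velocities))
    stop("insufficient-data: need >= 3 matched (velocity, delta) points",
         call. = FALSE)
  X <- cbind(v2 = velocities^2, v = velocities)
  fit <- stats::lm.fit(X, deltas)
  fitted <- X %*% fit$coefficients
  rss <- sum((deltas - fitted)^2)
  tss <- sum(deltas^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(a = unname(fit$coefficients["v2"]),
                 b = unname(fit$coefficients["v"]),
                 r_squared = r2, fitted = as.numeric(fitted)),
            class = "velocity_effect_fit")
}

#' @exportS3Method base::print
print.velocity_effect_fit <- function(x, ...) {
  cat(sprintf("delta = %.4g v^2 + %.4g v, R^2 = %.3g\n", x$a, x$b, x$r_squared))
  invisible(x)
}
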