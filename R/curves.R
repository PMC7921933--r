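#' Force-deformation curve
#'
#' Time-stamped probe force versus insertion depth record from a puncture
#' test (experimental), the synthetic generator, or a simulation.
#'
#' @param times Sample times (s), same length as the others.
#' @param depths Insertion depths (mm), non-decreasing.
#' @param forces Probe forces (N), finite and non-negative.
#' @param source One of \code{"experimental"}, \code{"synthetic"},
#'   \code{"simulated"}.
#' @return Object of class \code{force_deformation_curve}.
#' @export
force_deformation_curve <- function(times, depths, forces,
                                    source = c("experimental", "synthetic",
                                               "simulated")) {
  source <- match.arg(source)
  nlen <- length(times)
  if (length(depths) != nlen || length(forces) != nlen)
    stop("force_deformation_curve: times, depths, forces must have equal length",
         call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(depths)) || any(!is.finite(forces)))
    stop("force_deformation_curve: values must be finite", call. = FALSE)
  if (any(diff(depths) < -1e-12))
    stop("force_deformation_curve: depths must be non-decreasing", call. = FALSE)
  if (any(forces < 0))
    stop("force_deformation_curve: forces must be non-negative", call. = FALSE)
  structure(list(times = as.numeric(times), depths = as.numeric(depths),
                 forces = as.numeric(forces), source = source),
            class = "force_deformation_curve")
}

#' @exportS3Method base::print
print.force_deformation_curve <- function(x, ...) {
  cat(sprintf("Force-deformation curve (%s): %d samples, depth 0-%.3g mm, peak force %.4g N\n",
              x$source, length(x$forces), max(x$depths), max(x$forces)))
  invisible(x)
}

#' @export
as.data.frame.force_deformation_curve <- function(x, ...) {
  data.frame(time_s = x$times, depth_mm = x$depths, force_N = x$forces)
}

#' Write a force-deformation curve to CSV
#'
#' Columns \code{time_s, depth_mm, force_N}.
#'
#' @param curve A \code{\link{force_deformation_curve}}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, file) {
  stopifnot(inherits(curve, "force_deformation_curve"))
  utils::write.csv(as.data.frame(curve), file, row.names = FALSE)
  invisible(file)
}

#' Read a force-deformation curve from CSV
#'
#' @param file CSV path with columns \code{time_s, depth_mm, force_N}.
#' @param source Source tag for the curve, default \code{"experimental"}.
#' @return A \code{\link{force_deformation_curve}}.
#' @export
read_curve_csv <- function(file, source = "experimental") {
  df <- utils::read.csv(file)
  need <- c("time_s", "depth_mm", "force_N")
  if (!all(need %in% names(df)))
    stop("read_curve_csv: expected columns time_s, depth_mm, force_N",
         call. = FALSE)
  force_deformation_curve(df$time_s, df$depth_mm, df$force_N, source = source)
}
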