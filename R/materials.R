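#' Moisture content of an oven-dried sample
#'
#' Gravimetric moisture content on a wet basis: the mass lost during oven
#' drying as a percentage of the initial wet mass.
#'
#' @param wt1 Initial mass of the wet sample (g). Must be positive.
#' @param wt2 Mass of the oven-dried sample (g). Must satisfy
#'   \code{0 <= wt2 <= wt1}.
#' @return Moisture content in percent, in \code{[0, 100]}.
#' @examples
#' moisture_content(10, 1.5)   # 85
#' @export
moisture_content <- function(wt1, wt2) {
  if (!is.numeric(wt1) || !is.numeric(wt2) || !is.finite(wt1) || !is.finite(wt2))
    stop("moisture_content: masses must be finite numbers", call. = FALSE)
  if (wt1 <= 0)
    stop("invalid-measurement: wet mass wt1 must be positive", call. = FALSE)
  if (wt2 < 0 || wt2 > wt1)
    stop("invalid-measurement: dried mass wt2 must lie in [0, wt1]", call. = FALSE)
  (wt1 - wt2) / wt1 * 100
}

#' Poisson's ratio from moisture content
#'
#' Linear interpolation between the Poisson's ratio of fully dried tissue
#' (0.1) and fully fresh tissue (0.5):
#' \deqn{\nu = (0.5\,MC + 0.1\,(100 - MC)) / 100.}
#' The map is monotone increasing and takes \code{[0, 100]} onto
#' \code{[0.1, 0.5]}.
#'
#' @param MC Moisture content in percent, in \code{[0, 100]}. Vectorised.
#' @return Poisson's ratio (dimensionless).
#' @examples
#' poisson_from_moisture(85)   # 0.44, a typical fresh-papaya value
#' @export
poisson_from_moisture <- function(MC) {
  if (!is.numeric(MC) || any(!is.finite(MC)))
    stop("poisson_from_moisture: MC must be finite", call. = FALSE)
  if (any(MC < 0 | MC > 100))
    stop("poisson_from_moisture: MC must lie in [0, 100]", call. = FALSE)
  (0.5 * MC + 0.1 * (100 - MC)) / 100
}

#' Density of a cylindrical sample
#'
#' Mass over cylinder volume, reported in g/cm^3 for mass in grams and
#' dimensions in millimetres.
#'
#' @param mass Sample mass (g).
#' @param diameter Cylinder diameter (mm).
#' @param height Cylinder height (mm).
#' @return Density in g/cm^3.
#' @examples
#' density_from_cylinder(6.83, 20, 25)  # ~0.87 g/cm^3
#' @export
density_from_cylinder <- function(mass, diameter, height) {
  if (any(!is.finite(c(mass, diameter, height))) ||
      mass <= 0 || diameter <= 0 || height <= 0)
    stop("density_from_cylinder: all arguments must be positive", call. = FALSE)
  vol_mm3 <- pi * (diameter / 2)^2 * height
  mass / (vol_mm3 / 1000)  # mm^3 -> cm^3
}

#' Bilinear elastoplastic material parameters
#'
#' Parameter set for the bilinear (linear elastic, linear isotropic
#' hardening) constitutive law used for both skin and flesh tissue.
#' Perfect plasticity is the special case \code{Et = 0}.
#'
#' @param E Elastic modulus (MPa), positive.
#' @param sigma_y Yield stress (MPa), positive.
#' @param Et Tangent modulus beyond yield (MPa), \code{0 <= Et < E}.
#' @param nu Poisson's ratio, in \code{[0, 0.5)}.
#' @param rho Density (kg/m^3), positive. Converted internally by the
#'   solver to tonne/mm^3 for the mm-N-MPa-s unit system.
#' @return An object of class \code{material_params}.
#' @examples
#' material_params(E = 6, sigma_y = 2.5, Et = 0.03, nu = 0.44, rho = 1100)
#' @export
material_params <- function(E, sigma_y, Et, nu, rho) {
  vals <- c(E = E, sigma_y = sigma_y, Et = Et, nu = nu, rho = rho)
  if (any(!is.finite(vals)))
    stop("material_params: all fields must be finite", call. = FALSE)
  if (E <= 0) stop("material_params: E must be positive", call. = FALSE)
  if (sigma_y <= 0) stop("material_params: sigma_y must be positive", call. = FALSE)
  if (Et < 0 || Et >= E)
    stop("material_params: Et must satisfy 0 <= Et < E", call. = FALSE)
  if (nu < 0 || nu >= 0.5)
    stop("material_params: nu must lie in [0, 0.5)", call. = FALSE)
  if (rho <= 0) stop("material_params: rho must be positive", call. = FALSE)
  structure(list(E = E, sigma_y = sigma_y, Et = Et, nu = nu, rho = rho,
                 H = hardening_modulus(E, Et)),
            class = "material_params")
}

#' @exportS3Method base::print
print.material_params <- function(x, ...) {
  cat("Bilinear elastoplastic material\n")
  cat(sprintf("  E = %g MPa, sigma_y = %g MPa, Et = %g MPa (H = %g MPa)\n",
              x$E, x$sigma_y, x$Et, x$H))
  cat(sprintf("  nu = %g, rho = %g kg/m^3\n", x$nu, x$rho))
  invisible(x)
}

#' Uniaxial bilinear stress-strain law
#'
#' Engineering stress at a given monotonic uniaxial engineering strain:
#' \code{E * strain} up to the yield strain \code{sigma_y / E}, then
#' \code{sigma_y + Et * (strain - sigma_y / E)}. Continuous at yield,
#' non-decreasing, piecewise linear with slopes exactly \code{E} then
#' \code{Et}.
#'
#' @param strain Engineering strain(s), non-negative. Vectorised.
#' @param p A \code{\link{material_params}} object.
#' @return Stress in MPa.
#' @export
bilinear_stress <- function(strain, p) {
  stopifnot(inherits(p, "material_params"))
  if (any(!is.finite(strain)) || any(strain < 0))
    stop("bilinear_stress: strain must be non-negative (monotonic uniaxial convention)",
         call. = FALSE)
  eps_y <- p$sigma_y / p$E
  ifelse(strain <= eps_y, p$E * strain, p$sigma_y + p$Et * (strain - eps_y))
}

#' Isotropic hardening modulus of a bilinear law
#'
#' Converts the uniaxial tangent modulus \code{Et} to the plastic hardening
#' modulus \code{H = E * Et / (E - Et)} used by the radial-return stress
#' update. \code{H = 0} recovers perfect plasticity.
#'
#' @param E Elastic modulus (MPa).
#' @param Et Tangent modulus (MPa), \code{0 <= Et < E}.
#' @return Hardening modulus H (MPa).
#' @export
hardening_modulus <- function(E, Et) {
  if (!is.finite(E) || !is.finite(Et) || E <= 0)
    stop("hardening_modulus: E must be positive and both arguments finite",
         call. = FALSE)
  if (Et < 0 || Et >= E)
    stop("invalid-hardening: require 0 <= Et < E", call. = FALSE)
  E * Et / (E - Et)
}

#' Tangent modulus from elastic and hardening moduli
#'
#' Inverse of \code{\link{hardening_modulus}}: \code{Et = E * H / (E + H)}.
#'
#' @param E Elastic modulus (MPa).
#' @param H Hardening modulus (MPa), non-negative.
#' @return Tangent modulus Et (MPa).
#' @export
tangent_from_hardening <- function(E, H) {
  if (!is.finite(E) || !is.finite(H) || E <= 0 || H < 0)
    stop("tangent_from_hardening: require E > 0 and H >= 0", call. = FALSE)
  E * H / (E + H)
}

# Measured min/avg/max levels of the tissue mechanical properties, per layer.
# Shipped verbatim as inst/extdata/table_material_levels.csv; kept here too so
# the lookup needs no file I/O.
.material_levels <- local({
  df <- expand.grid(level = c("min", "avg", "max"),
                    tissue = c("skin", "flesh"),
                    stringsAsFactors = FALSE)[, 2:1]
  df$E <- c(2, 6, 15, 0.5, 2, 4)
  df$sigma_y <- c(0.5, 2.5, 4, 0.05, 1, 1.8)
  df$Et <- c(0.02, 0.03, 0.04, 0.002, 0.003, 0.004)
  df$nu <- c(0.43, 0.44, 0.45, 0.43, 0.44, 0.45)
  df$rho <- c(1000, 1100, 1200, 1000, 1100, 1200)
  df
})

#' Measured material-property levels for papaya skin and flesh
#'
#' The min/avg/max levels of elastic modulus, yield stress, tangent modulus,
#' Poisson's ratio and density measured for papaya skin and flesh, used as
#' bounds and defaults for the puncture model.
#'
#' @param tissue Either \code{"skin"} or \code{"flesh"}.
#' @param level One of \code{"min"}, \code{"avg"}, \code{"max"}.
#' @return A \code{\link{material_params}} object for that cell.
#' @examples
#' material_level_params("skin", "avg")
#' @export
material_level_params <- function(tissue, level) {
  if (!is.character(tissue) || length(tissue) != 1L ||
      !tissue %in% c("skin", "flesh"))
    stop("material_level_params: unknown tissue '", tissue,
         "' (expected 'skin' or 'flesh')", call. = FALSE)
  if (!is.character(level) || length(level) != 1L ||
      !level %in% c("min", "avg", "max"))
    stop("material_level_params: unknown level '", level,
         "' (expected 'min', 'avg' or 'max')", call. = FALSE)
  row <- .material_levels[.material_levels$tissue == tissue &
                          .material_levels$level == level, ]
  material_params(E = row$E, sigma_y = row$sigma_y, Et = row$Et,
                  nu = row$nu, rho = row$rho)
}

#' All material-property levels as a data frame
#'
#' @return Data frame with columns tissue, level, E, sigma_y, Et, nu, rho.
#' @export
material_levels <- function() .material_levels

#' Stress-strain record
#'
#' A pair of matched engineering strain/stress vectors from a uniaxial
#' (compression or tensile) test.
#'
#' @param strains Strictly increasing strains starting at 0 (dimensionless).
#' @param stresses Matching stresses (MPa).
#' @return Object of class \code{stress_strain_record}.
#' @export
stress_strain_record <- function(strains, stresses) {
  if (length(strains) != length(stresses) || length(strains) < 2)
    stop("stress_strain_record: need matched vectors of length >= 2",
         call. = FALSE)
  if (any(!is.finite(strains)) || any(!is.finite(stresses)))
    stop("stress_strain_record: values must be finite", call. = FALSE)
  if (strains[1] != 0 || any(diff(strains) <= 0))
    stop("stress_strain_record: strains must be strictly increasing from 0",
         call. = FALSE)
  structure(list(strains = as.numeric(strains), stresses = as.numeric(stresses)),
            class = "stress_strain_record")
}

#' Fit a bilinear elastoplastic law to a stress-strain record
#'
#' Detects the linear elastic region as the longest prefix whose
#' least-squares line through the origin keeps every residual below
#' \code{tol} times the maximum stress; the break point is the first
#' departure. The elastic modulus is the prefix slope, the tangent modulus
#' the slope of the remaining points, and the yield stress is taken at the
#' intersection of the two fitted lines (so noise-free bilinear data are
#' recovered exactly).
#'
#' @param record A \code{\link{stress_strain_record}}.
#' @param tol Relative residual tolerance defining the linear region,
#'   as a fraction of the maximum stress. Default 0.01.
#' @return List with elements \code{E}, \code{sigma_y}, \code{Et} and
#'   \code{yield_detected}. When no slope break is found within the record
#'   (pure linear input), \code{sigma_y} and \code{Et} are \code{NA} and
#'   \code{yield_detected} is \code{FALSE}.
#' @export
fit_bilinear <- function(record, tol = 0.01) {
  stopifnot(inherits(record, "stress_strain_record"))
  eps <- record$strains
  sig <- record$stresses
  n <- length(eps)
  if (n < 2)
    stop("insufficient-data: need at least 2 points", call. = FALSE)
  smax <- max(abs(sig))
  if (smax == 0)
    stop("insufficient-data: all stresses are zero", call. = FALSE)
  band <- tol * smax

  # longest prefix (from the 2nd point) fitting a line through the origin
  slope_prefix <- function(k) sum(eps[1:k] * sig[1:k]) / sum(eps[1:k]^2)
  k_lin <- 2L
  for (k in 2:n) {
    sl <- slope_prefix(k)
    if (max(abs(sig[1:k] - sl * eps[1:k])) > band) break
    k_lin <- k
  }
  E_hat <- slope_prefix(k_lin)

  if (k_lin >= n - 1L) {
    # fewer than 2 points beyond the linear region: elastic-only fit
    return(list(E = E_hat, sigma_y = NA_real_, Et = NA_real_,
                yield_detected = FALSE))
  }

  idx <- (k_lin + 1L):n
  pfit <- stats::lm.fit(cbind(1, eps[idx]), sig[idx])
  c0 <- pfit$coefficients[1]
  Et_hat <- pfit$coefficients[2]
  if (!is.finite(Et_hat) || Et_hat >= E_hat) {
    # no genuine slope break (second branch at least as stiff): treat as linear
    return(list(E = slope_prefix(n), sigma_y = NA_real_, Et = NA_real_,
                yield_detected = FALSE))
  }
  Et_hat <- max(Et_hat, 0)
  sigma_y_hat <- E_hat * c0 / (E_hat - Et_hat)
  list(E = unname(E_hat), sigma_y = unname(sigma_y_hat),
       Et = unname(Et_hat), yield_detected = TRUE)
}
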