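# Seeded generators for surrogate experimental data. All generators are pure
# functions of their arguments: the global RNG state is saved and restored.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic puncture force-deformation curve
#'
#' Emulates a flat-probe puncture record: a linear force rise to the
#' bioyield peak, a sharp drop over a short ramp, then a fluctuating plateau
#' (bounded sinusoid plus multiplicative Gaussian noise) out to the maximum
#' insertion depth, sampled uniformly in time with depth = velocity x time.
#' When the uniform grid misses the exact bioyield depth, the exact peak
#' sample is inserted so the generator's (force, deformation) pair is always
#' recoverable from the curve. Deterministic given the seed.
#'
#' @param bioyield_force Peak (bioyield) force F_b (N).
#' @param bioyield_deformation Depth of the peak d_b (mm).
#' @param plateau_level Post-drop plateau force as a fraction of F_b,
#'   in (0, 1). Default 0.55.
#' @param fluctuation_amplitude Plateau sinusoid amplitude as a fraction of
#'   the plateau force, in (0, 1). Default 0.06.
#' @param velocity Probe velocity (mm/s). Default 1.5.
#' @param max_depth Maximum insertion depth (mm). Default 10.
#' @param sampling_rate Samples per second. Default 200.
#' @param noise_sd Multiplicative Gaussian force noise (fraction). Default 0.
#' @param seed Integer seed. Default 1.
#' @param drop_width Depth interval of the post-bioyield force drop (mm).
#'   Default 0.15.
#' @return A \code{\link{force_deformation_curve}} with source
#'   \code{"synthetic"}.
#' @export
synth_puncture_curve <- function(bioyield_force, bioyield_deformation,
                                 plateau_level = 0.55,
                                 fluctuation_amplitude = 0.06,
                                 velocity = 1.5, max_depth = 10,
                                 sampling_rate = 200, noise_sd = 0,
                                 seed = 1, drop_width = 0.15) {
  if (bioyield_force <= 0 || bioyield_deformation <= 0 || velocity <= 0 ||
      max_depth <= 0 || sampling_rate <= 0 || noise_sd < 0)
    stop("invalid-spec: spec fields must be positive (noise_sd >= 0)",
         call. = FALSE)
  if (plateau_level <= 0 || plateau_level >= 1 ||
      fluctuation_amplitude < 0 || fluctuation_amplitude >= 1)
    stop("invalid-spec: fractions must lie in (0, 1)", call. = FALSE)
  if (bioyield_deformation >= max_depth)
    stop("invalid-spec: bioyield deformation must be below the maximum depth",
         call. = FALSE)
  # depth grid with the exact bioyield sample on it: snap the nearest grid
  # point (or insert one), so the generator's peak is always recoverable
  step <- velocity / sampling_rate
  depths <- (0:floor(max_depth / step)) * step
  i_b <- which.min(abs(depths - bioyield_deformation))
  if (abs(depths[i_b] - bioyield_deformation) < 1e-9 * max(1, bioyield_deformation))
    depths[i_b] <- bioyield_deformation
  else
    depths <- sort(c(depths, bioyield_deformation))
  times <- depths / velocity

  F_b <- bioyield_force
  d_b <- bioyield_deformation
  Fpl <- plateau_level * F_b
  base <- numeric(length(depths))
  rise <- depths <= d_b
  base[rise] <- F_b * (depths[rise] / d_b)  # grouped so the peak is exact
  drop <- depths > d_b & depths <= d_b + drop_width
  base[drop] <- F_b + (Fpl - F_b) * (depths[drop] - d_b) / drop_width
  plat <- depths > d_b + drop_width
  base[plat] <- Fpl * (1 + fluctuation_amplitude *
                         sin(2 * pi * (depths[plat] - d_b) / 0.5))
  forces <- .with_seed(seed, {
    noise <- if (noise_sd > 0) stats::rnorm(length(base), 0, noise_sd) else 0
    base * (1 + noise)
  })
  force_deformation_curve(times, depths, pmax(forces, 0), source = "synthetic")
}

#' Synthetic material-property samples
#'
#' Draws material parameter sets from independent truncated normal
#' distributions (truncated to each field's physical validity range, with
#' the tangent modulus additionally truncated below each draw's elastic
#' modulus), mirroring properties reported as mean plus/minus standard
#' error. Deterministic given the seed.
#'
#' @param means Named numeric vector or list with entries \code{E},
#'   \code{sigma_y}, \code{Et}, \code{nu}, \code{rho} (units as in
#'   \code{\link{material_params}}).
#' @param ses Standard errors for the same fields (0 allowed: degenerate at
#'   the mean).
#' @param n Number of samples, >= 1.
#' @param seed Integer seed.
#' @return List of \code{n} \code{\link{material_params}} objects.
#' @export
synth_property_samples <- function(means, ses, n, seed = 1) {
  means <- as.list(means); ses <- as.list(ses)
  need <- c("E", "sigma_y", "Et", "nu", "rho")
  if (!all(need %in% names(means)) || !all(need %in% names(ses)))
    stop("invalid-spec: means and ses need fields E, sigma_y, Et, nu, rho",
         call. = FALSE)
  if (n < 1) stop("invalid-spec: n must be >= 1", call. = FALSE)
  bounds <- list(E = c(1e-9, Inf), sigma_y = c(1e-9, Inf), Et = c(0, Inf),
                 nu = c(0.1, 0.5 - 1e-9), rho = c(1e-9, Inf))
  for (f in need) {
    b <- bounds[[f]]
    if (means[[f]] < b[1] || means[[f]] > b[2])
      stop("invalid-spec: mean of ", f, " lies outside its validity range",
           call. = FALSE)
    if (ses[[f]] < 0)
      stop("invalid-spec: standard errors must be non-negative", call. = FALSE)
  }
  rtrunc <- function(n, mean, sd, lo, hi) {
    if (sd == 0) return(rep(mean, n))
    p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
    pmin(pmax(stats::qnorm(p, mean, sd), lo), hi)
  }
  .with_seed(seed, {
    E <- rtrunc(n, means$E, ses$E, bounds$E[1], bounds$E[2])
    sy <- rtrunc(n, means$sigma_y, ses$sigma_y, bounds$sigma_y[1], Inf)
    nu <- rtrunc(n, means$nu, ses$nu, bounds$nu[1], bounds$nu[2])
    rho <- rtrunc(n, means$rho, ses$rho, bounds$rho[1], Inf)
    Et <- vapply(seq_len(n), function(i)
      rtrunc(1, means$Et, ses$Et, 0, E[i] * (1 - 1e-9)), numeric(1))
    lapply(seq_len(n), function(i)
      material_params(E = E[i], sigma_y = sy[i], Et = Et[i],
                      nu = nu[i], rho = rho[i]))
  })
}

#' Synthetic bilinear stress-strain record
#'
#' Samples the bilinear law of a parameter set on a uniform strain grid with
#' multiplicative Gaussian stress noise; the standard fixture generator for
#' \code{\link{fit_bilinear}}. Deterministic given the seed.
#'
#' @param p A \code{\link{material_params}} object.
#' @param max_strain Largest strain sampled; should exceed the yield strain
#'   \code{sigma_y / E} for two-branch coverage.
#' @param n_points Number of samples (>= 2). Default 50.
#' @param noise_sd Multiplicative stress noise (fraction). Default 0.
#' @param seed Integer seed. Default 1.
#' @return A \code{\link{stress_strain_record}}.
#' @export
synth_bilinear_record <- function(p, max_strain, n_points = 50, noise_sd = 0,
                                  seed = 1) {
  stopifnot(inherits(p, "material_params"))
  if (!is.finite(max_strain) || max_strain <= 0)
    stop("invalid-spec: max_strain must be positive", call. = FALSE)
  strains <- seq(0, max_strain, length.out = n_points)
  stresses <- bilinear_stress(strains, p)
  if (noise_sd > 0)
    stresses <- .with_seed(seed,
      stresses * (1 + stats::rnorm(length(stresses), 0, noise_sd)))
  stress_strain_record(strains, stresses)
}
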