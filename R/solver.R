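#' Rigid flat-end probe specification
#'
#' @param radius Probe radius (mm). Default 1 (2 mm diameter flat punch).
#' @param velocity Probe insertion velocity (mm/s).
#' @param max_insertion Maximum insertion depth (mm). Default 10.
#' @return Object of class \code{probe_spec}.
#' @export
probe_spec <- function(radius = 1, velocity = 1.5, max_insertion = 10) {
  if (any(!is.finite(c(radius, velocity, max_insertion))) ||
      radius <= 0 || velocity <= 0 || max_insertion <= 0)
    stop("probe_spec: all fields must be positive", call. = FALSE)
  structure(list(radius = radius, velocity = velocity,
                 max_insertion = max_insertion), class = "probe_spec")
}

#' Solver configuration
#'
#' Controls for the implicit quasi-static and explicit dynamic puncture
#' solvers. All solvers are fully deterministic.
#'
#' @param mode \code{"quasi_static"} or \code{"explicit"}.
#' @param penalty_scale Contact penalty stiffness scale: the nodal penalty is
#'   \code{penalty_scale} times the stiffness of the adjacent element column
#'   (E * tributary area / element height). Default 100.
#' @param epsp_max Element-erosion equivalent plastic strain limit. Elements
#'   whose maximum integration-point plastic strain reaches this value are
#'   permanently deleted. Default 0.5.
#' @param dd Quasi-static punch-depth increment (mm). Default 0.02.
#' @param newton_tol Relative residual tolerance of the Newton loop.
#' @param newton_maxit Maximum Newton iterations per increment.
#' @param safety CFL safety factor for the explicit time step, in (0, 1].
#' @param time_scale Explicit-mode velocity scaling factor: the punch is run
#'   at \code{velocity * time_scale} to shorten the simulated interval, valid
#'   while kinetic effects stay small. Default 1 (no scaling).
#' @param damping Mass-proportional damping coefficient (1/s) for explicit
#'   mode. Default 0. The magnitude of physical damping in fruit tissue is
#'   uncalibrated; this knob exists for noise control only.
#' @param filter_window Moving-average window (samples) applied to the
#'   explicit-mode force history for reporting. Default 9.
#' @param ramp_frac Fraction of the explicit run spent smoothly ramping the
#'   punch velocity from zero, suppressing the startup impact transient.
#'   Default 0.05.
#' @param max_steps Hard cap on explicit steps. Default 2e6.
#' @return Object of class \code{solver_config}.
#' @export
solver_config <- function(mode = c("quasi_static", "explicit"),
                          penalty_scale = 100, epsp_max = 0.5, dd = 0.02,
                          newton_tol = 1e-5, newton_maxit = 40,
                          safety = 0.9, time_scale = 1, damping = 0,
                          filter_window = 9, ramp_frac = 0.05,
                          max_steps = 2e6) {
  mode <- match.arg(mode)
  if (penalty_scale <= 0 || epsp_max <= 0 || dd <= 0 || newton_tol <= 0)
    stop("solver_config: scales, tolerances, increments must be positive",
         call. = FALSE)
  if (safety <= 0 || safety > 1)
    stop("solver_config: safety factor must lie in (0, 1]", call. = FALSE)
  structure(list(mode = mode, penalty_scale = penalty_scale,
                 epsp_max = epsp_max, dd = dd, newton_tol = newton_tol,
                 newton_maxit = newton_maxit, safety = safety,
                 time_scale = time_scale, damping = damping,
                 filter_window = filter_window, ramp_frac = ramp_frac,
                 max_steps = max_steps),
            class = "solver_config")
}

# kg/m^3 -> tonne/mm^3 (mm-N-MPa-s unit system)
.rho_solver <- function(rho_kg_m3) rho_kg_m3 * 1e-12

#' Stable explicit time step estimate
#'
#' CFL bound \code{safety * h / c} with the bar wave speed
#' \code{c = sqrt(E / rho)} in the mm-N-MPa-s system (density converted from
#' kg/m^3 to tonne/mm^3). The explicit driver additionally accounts for the
#' constrained-modulus wave speed and contact springs; this function is the
#' conventional hand estimate.
#'
#' @param h Smallest element edge length (mm).
#' @param E Elastic modulus (MPa).
#' @param rho Density (kg/m^3).
#' @param safety Safety factor, default 0.9.
#' @return Time step in seconds.
#' @examples
#' stable_time_step(1, 6, 1100)  # ~1.22e-5 s
#' @export
stable_time_step <- function(h, E, rho, safety = 0.9) {
  if (any(c(h, E, rho) <= 0) || safety <= 0 || safety > 1)
    stop("stable_time_step: invalid arguments", call. = FALSE)
  c_bar <- sqrt(E / .rho_solver(rho))
  safety * h / c_bar
}

#' Single-point radial-return stress update
#'
#' J2 (von Mises) return mapping with linear isotropic hardening
#' \code{H = E Et / (E - Et)} for one integration point. Stress and strain
#' use Voigt order (rr, zz, tt, rz) with engineering shear strain.
#'
#' @param strain_increment Strain increment, length-4 numeric.
#' @param state List with \code{sig} (length-4 stress, MPa) and \code{epsp}
#'   (equivalent plastic strain).
#' @param p A \code{\link{material_params}} object.
#' @return Updated state list with \code{sig}, \code{epsp}, plastic
#'   multiplier \code{dgamma} and von Mises stress \code{vm}.
#' @export
radial_return <- function(strain_increment, state, p) {
  stopifnot(inherits(p, "material_params"))
  if (is.null(state$sig)) state$sig <- numeric(4)
  if (is.null(state$epsp)) state$epsp <- 0
  if (any(!is.finite(strain_increment)) || any(!is.finite(state$sig)) ||
      !is.finite(state$epsp))
    stop("numerical-state: non-finite input to radial_return", call. = FALSE)
  cpp_radial_return(as.numeric(state$sig), as.numeric(strain_increment),
                    state$epsp, p$E, p$nu, p$sigma_y, p$H)
}

#' Erode elements exceeding the plastic-strain limit
#'
#' Deactivates every active element whose maximum integration-point
#' equivalent plastic strain has reached \code{config$epsp_max} (closed
#' threshold) and zeroes its stresses. Deactivation is permanent.
#'
#' @param state List with \code{active} (logical per element), \code{epsp}
#'   (ne x ngp matrix) and optionally \code{sig} (ne x 4*ngp matrix).
#' @param config A \code{\link{solver_config}}.
#' @return The updated state, plus \code{newly_eroded} element indices.
#' @export
erode_elements <- function(state, config) {
  epsp_el <- apply(as.matrix(state$epsp), 1, max)
  newly <- which(state$active & epsp_el >= config$epsp_max)
  state$active[newly] <- FALSE
  if (!is.null(state$sig) && length(newly)) state$sig[newly, ] <- 0
  state$newly_eroded <- newly
  state
}

#' Flat-punch contact forces on the exposed surface
#'
#' Frictionless normal penalty contact between the rigid flat punch (face at
#' \code{z = depth_top - punch_depth}, footprint \code{r <= probe$radius})
#' and the currently exposed top surface of the active mesh. Nodes uncovered
#' by element erosion become contact candidates (eroding contact). The punch
#' pushes penetrating nodes in -z; the equal and opposite reaction on the
#' punch (the recorded puncture force) acts in +z with magnitude
#' \code{penalty * penetration} per node.
#'
#' @param punch_depth Current punch insertion depth (mm), >= 0.
#' @param mesh A \code{\link{build_mesh}} result (its \code{active} flags
#'   define the exposed surface unless \code{state$active} is given).
#' @param state List with nodal displacement matrix \code{u} (n x 2, mm) and
#'   optionally \code{active} element flags.
#' @param probe A \code{\link{probe_spec}}.
#' @param penalty Penalty stiffness per node (N/mm), scalar or per-node.
#' @return List with \code{candidates} (node indices under the punch and
#'   exposed), \code{penetration}, per-node punch reaction \code{force}
#'   (N, magnitude), nodal tissue force z-component \code{fz_node} (N,
#'   negative), and \code{total_force} (N, punch reaction, +z).
#' @export
contact_update <- function(punch_depth, mesh, state, probe, penalty) {
  stopifnot(inherits(mesh, "puncture_mesh"), punch_depth >= 0)
  active <- if (!is.null(state$active)) state$active else mesh$active
  surf <- cpp_surface_info(active, mesh$nr, mesh$nz)
  u <- state$u
  if (is.null(u)) u <- matrix(0, nrow(mesh$nodes), 2)
  r <- mesh$nodes[, 1]
  h_r <- min(diff(mesh$r_breaks))
  under <- r <= probe$radius + 0.25 * h_r
  cand <- which(surf$candidate & under)
  z_face <- mesh$spec$depth - punch_depth
  pen <- (mesh$nodes[cand, 2] + u[cand, 2]) - z_face
  keep <- pen > 0
  cand <- cand[keep]
  pen <- pen[keep]
  k <- if (length(penalty) == 1) rep(penalty, length(cand)) else penalty[cand]
  f <- k * pen
  list(candidates = cand, penetration = pen, force = f,
       fz_node = -f, total_force = sum(f))
}

# ---- internal solver plumbing -----------------------------------------------

# materials: list(skin = material_params, flesh = material_params)
.props_matrix <- function(materials) {
  rbind(skin = c(materials$skin$E, materials$skin$nu, materials$skin$sigma_y,
                 materials$skin$H, .rho_solver(materials$skin$rho)),
        flesh = c(materials$flesh$E, materials$flesh$nu, materials$flesh$sigma_y,
                  materials$flesh$H, .rho_solver(materials$flesh$rho)))
}

.solver_setup <- function(mesh, materials, probe, config) {
  nodes <- mesh$nodes
  n <- nrow(nodes)
  r <- nodes[, 1]; z <- nodes[, 2]
  fixed <- rep(FALSE, 2 * n)
  tol <- 1e-9
  bottom <- z < tol
  fixed[2 * which(bottom) - 1] <- TRUE
  fixed[2 * which(bottom)] <- TRUE
  fixed[2 * which(r < tol) - 1] <- TRUE                    # axis symmetry
  fixed[2 * which(r > mesh$spec$radius - tol) - 1] <- TRUE # outer radius

  # per-node penalty stiffness ~ penalty_scale x adjacent column stiffness
  h_r <- min(diff(mesh$r_breaks))
  h_z <- min(diff(mesh$z_breaks))
  dr <- diff(mesh$r_breaks)
  trib <- numeric(length(mesh$r_breaks))
  trib[1] <- pi * (dr[1] / 2)^2
  nr1 <- length(mesh$r_breaks)
  for (i in 2:nr1) {
    lo <- mesh$r_breaks[i] - dr[i - 1] / 2
    hi <- if (i < nr1) mesh$r_breaks[i] + dr[i] / 2 else mesh$r_breaks[i]
    trib[i] <- pi * (hi^2 - lo^2)
  }
  Emax <- max(materials$skin$E, materials$flesh$E)
  i_rad <- match(round(r, 9), round(mesh$r_breaks, 9))
  knode <- config$penalty_scale * Emax * trib[i_rad] / h_z
  cand_rad <- r <= probe$radius + 0.25 * h_r

  list(fixed = fixed, knode = knode, cand_rad = cand_rad,
       props = .props_matrix(materials), h_r = h_r, h_z = h_z)
}

.vm_element <- function(vm_gp) rowMeans(vm_gp)

.new_result <- function(mesh, probe, config, times, depths, forces, snapshots,
                        eroded, flags, state) {
  curve <- force_deformation_curve(times = times, depths = depths,
                                   forces = pmax(forces, 0),
                                   source = "simulated")
  structure(list(curve = curve, snapshots = snapshots, eroded = eroded,
                 flags = flags, mesh = mesh, probe = probe, config = config,
                 state = state),
            class = "simulation_result")
}

#' @exportS3Method base::print
print.simulation_result <- function(x, ...) {
  cat(sprintf("Puncture simulation (%s): %d increments to depth %.3g mm, peak force %.4g N\n",
              x$config$mode, length(x$curve$forces), max(x$curve$depths),
              max(x$curve$forces)))
  if (length(x$eroded$elem)) cat(sprintf("  %d elements eroded\n", length(x$eroded$elem)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Implicit quasi-static puncture simulation
#'
#' Displacement-controlled punch insertion solved by full Newton iteration
#' with the consistent elastoplastic tangent at each depth increment.
#' Boundary conditions: bottom face fully fixed, radial displacement fixed on
#' the symmetry axis and the outer radius. Elements exceeding the
#' plastic-strain erosion limit are deleted after each converged increment
#' and equilibrium is re-established at the same depth, which produces the
#' post-bioyield force drop. The constitutive law is rate-independent, so
#' the probe velocity enters only through the reported time column.
#'
#' @param mesh A \code{\link{build_mesh}} result.
#' @param materials List with \code{skin} and \code{flesh}
#'   \code{\link{material_params}}.
#' @param probe A \code{\link{probe_spec}}.
#' @param config A \code{\link{solver_config}} with mode
#'   \code{"quasi_static"}.
#' @param snapshot_depths Depths (mm) at which to store displacement, von
#'   Mises stress and plastic-strain fields.
#' @return A \code{simulation_result}: \code{curve}
#'   (\code{\link{force_deformation_curve}}), \code{snapshots},
#'   \code{eroded} history, solver \code{flags} and the final \code{state}.
#' @export
solve_quasi_static <- function(mesh, materials, probe,
                               config = solver_config("quasi_static"),
                               snapshot_depths = numeric(0)) {
  stopifnot(inherits(mesh, "puncture_mesh"), inherits(probe, "probe_spec"))
  if (config$mode != "quasi_static")
    stop("solve_quasi_static: config mode must be 'quasi_static'", call. = FALSE)
  setup <- .solver_setup(mesh, materials, probe, config)
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems); ndof <- 2 * n
  z_top <- mesh$spec$depth

  st <- list(u = numeric(ndof), sig = matrix(0, ne, 16),
             epsp = matrix(0, ne, 4), active = mesh$active)
  surf <- cpp_surface_info(st$active, mesh$nr, mesh$nz)

  free_dofs <- function(active, attached) {
    fx <- setup$fixed
    orphan <- which(!attached)
    if (length(orphan)) { fx[2 * orphan - 1] <- TRUE; fx[2 * orphan] <- TRUE }
    which(!fx)
  }

  contact_forces <- function(u, depth, candidate) {
    cand <- which(candidate & setup$cand_rad)
    z_face <- z_top - depth
    pen <- (mesh$nodes[cand, 2] + u[2 * cand]) - z_face
    keep <- pen > 0
    list(idx = cand[keep], pen = pen[keep], k = setup$knode[cand[keep]])
  }

  newton <- function(u, depth, candidate, attached) {
    free <- free_dofs(st$active, attached)
    eval_point <- function(u) {
      asm <- cpp_assemble(mesh$nodes, mesh$elems, st$active, mesh$mat,
                          setup$props, u, st$u, st$sig, st$epsp, TRUE)
      ct <- contact_forces(u, depth, candidate)
      resid <- -asm$fint
      if (length(ct$idx)) resid[2 * ct$idx] <- resid[2 * ct$idx] - ct$k * ct$pen
      list(asm = asm, ct = ct, resid = resid,
           rnorm = max(abs(resid[free])),
           force = sum(ct$k * ct$pen))
    }
    ep <- eval_point(u)
    bad <- 0L
    for (it in seq_len(config$newton_maxit)) {
      fc_scale <- max(1e-3, ep$force)
      if (ep$rnorm <= config$newton_tol * fc_scale)
        return(list(u = u, asm = ep$asm, converged = TRUE, niter = it,
                    force = ep$force))
      K <- Matrix::sparseMatrix(i = ep$asm$ki, j = ep$asm$kj, x = ep$asm$kv,
                                dims = c(ndof, ndof))
      if (length(ep$ct$idx)) {
        zi <- 2 * ep$ct$idx
        K <- K + Matrix::sparseMatrix(i = zi, j = zi, x = ep$ct$k,
                                      dims = c(ndof, ndof))
      }
      du <- numeric(ndof)
      sol <- try(Matrix::solve(K[free, free, drop = FALSE], ep$resid[free]),
                 silent = TRUE)
      if (inherits(sol, "try-error")) break
      du[free] <- as.numeric(sol)
      # backtracking line search on the residual norm: erosion and contact
      # set changes can make the full Newton step overshoot
      accepted <- FALSE
      for (alpha in c(1, 0.5, 0.25, 0.1, 0.05)) {
        ep_try <- try(eval_point(u + alpha * du), silent = TRUE)
        if (inherits(ep_try, "try-error")) next
        if (ep_try$rnorm < 0.999 * ep$rnorm) {
          u <- u + alpha * du
          ep <- ep_try
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        ep_try <- try(eval_point(u + 0.05 * du), silent = TRUE)
        if (inherits(ep_try, "try-error")) break
        u <- u + 0.05 * du
        ep <- ep_try
        bad <- bad + 1L
        if (bad >= 4L) break
      } else bad <- 0L
    }
    list(u = u, asm = ep$asm, converged = FALSE, niter = config$newton_maxit,
         force = ep$force)
  }

  depths <- forces <- numeric(0)
  snapshots <- list()
  eroded <- list(depth = numeric(0), elem = integer(0))
  flags <- character(0)
  snap_left <- sort(snapshot_depths)
  depth <- 0
  dd <- config$dd
  dd_min <- config$dd / 64
  u <- st$u

  while (depth < probe$max_insertion - 1e-12) {
    step <- min(dd, probe$max_insertion - depth)
    trial_depth <- depth + step
    ns <- newton(u, trial_depth, surf$candidate, surf$attached)
    if (!ns$converged) {
      if (step / 2 >= dd_min) { dd <- step / 2; next }
      flags <- c(flags, sprintf("non-convergence at depth %.4g mm; stopped with last converged state", trial_depth))
      break
    }
    dd <- min(config$dd, dd * 2)
    depth <- trial_depth
    u <- ns$u
    # commit
    st$u <- u
    st$sig <- ns$asm$sig
    st$epsp <- ns$asm$epsp
    depths <- c(depths, depth)
    forces <- c(forces, ns$force)
    vm_el <- .vm_element(ns$asm$vm)

    # erosion (closed threshold), then re-equilibrate at the same depth;
    # deletion may cascade, so cycle erosion/equilibrium a few times
    epsp_el <- ns$asm$epsp_el_max
    for (cycle in 1:6) {
      newly <- which(st$active & epsp_el >= config$epsp_max)
      if (!length(newly)) break
      st$active[newly] <- FALSE
      st$sig[newly, ] <- 0
      eroded$depth <- c(eroded$depth, rep(depth, length(newly)))
      eroded$elem <- c(eroded$elem, newly)
      surf <- cpp_surface_info(st$active, mesh$nr, mesh$nz)
      re <- newton(u, depth, surf$candidate, surf$attached)
      if (re$converged) {
        u <- re$u
        st$u <- u
        st$sig <- re$asm$sig
        st$epsp <- re$asm$epsp
        epsp_el <- re$asm$epsp_el_max
        depths <- c(depths, depth)
        forces <- c(forces, re$force)
        vm_el <- .vm_element(re$asm$vm)
      } else {
        flags <- c(flags, sprintf("post-erosion re-equilibration did not converge at depth %.4g mm", depth))
        break
      }
    }
    while (length(snap_left) && depth >= snap_left[1] - 1e-12) {
      snapshots[[length(snapshots) + 1]] <-
        list(depth = depth, time = depth / probe$velocity,
             u = matrix(u, ncol = 2, byrow = TRUE),
             vm = vm_el, epsp = ns$asm$epsp_el_max, active = st$active)
      snap_left <- snap_left[-1]
    }
  }
  mesh$active <- st$active
  .new_result(mesh, probe, config, times = depths / probe$velocity,
              depths = depths, forces = forces, snapshots = snapshots,
              eroded = eroded, flags = flags, state = st)
}

#' Explicit dynamic puncture simulation
#'
#' Central-difference time integration with lumped mass, the same radial
#' return, eroding contact and erosion operators as the quasi-static driver.
#' The punch advances at \code{probe$velocity * config$time_scale}; inertia
#' is the only velocity-dependent mechanism (the constitutive law is
#' rate-independent). The reported force history is smoothed with a moving
#' average of \code{config$filter_window} samples; the raw history is kept in
#' \code{curve_raw}.
#'
#' @inheritParams solve_quasi_static
#' @return A \code{simulation_result} (with extra element \code{curve_raw}).
#' @export
solve_explicit <- function(mesh, materials, probe,
                           config = solver_config("explicit")) {
  stopifnot(inherits(mesh, "puncture_mesh"), inherits(probe, "probe_spec"))
  if (config$mode != "explicit")
    stop("solve_explicit: config mode must be 'explicit'", call. = FALSE)
  setup <- .solver_setup(mesh, materials, probe, config)
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)

  # lumped mass: element mass (rho * area * 2 pi r_centroid) split equally
  areas <- .element_areas(mesh)
  rc <- rowMeans(matrix(mesh$nodes[t(mesh$elems), 1], ncol = 4, byrow = TRUE))
  rho_el <- setup$props[mesh$mat, 5]
  me <- rho_el * areas * 2 * pi * pmax(rc, 1e-6)
  mass_n <- numeric(n)
  for (a in 1:4) {
    idx <- mesh$elems[, a]
    mass_n[idx] <- mass_n[idx] + me / 4 * mesh$active
  }
  mass <- rep(mass_n, each = 2)

  # time step: constrained-modulus wave speed and contact springs
  cps <- apply(setup$props, 1, function(p)
    sqrt(p[1] * (1 - p[2]) / ((1 + p[2]) * (1 - 2 * p[2])) / p[5]))
  h_min <- min(setup$h_r, setup$h_z)
  dt_el <- config$safety * h_min / max(cps)
  cand <- which(setup$cand_rad & mass_n > 0)
  dt_ct <- if (length(cand))
    config$safety * min(2 / sqrt(setup$knode[cand] / mass_n[cand])) / 2 else Inf
  dt <- min(dt_el, dt_ct)

  v_eff <- probe$velocity * config$time_scale
  ramp_time <- config$ramp_frac * probe$max_insertion / v_eff
  t_end <- probe$max_insertion / v_eff + ramp_time / 2
  nsteps <- ceiling(t_end / dt)
  if (nsteps > config$max_steps)
    stop("solve_explicit: required steps exceed max_steps; increase time_scale or coarsen",
         call. = FALSE)
  record_every <- max(1L, floor(nsteps / 4000))

  res <- cpp_explicit_run(mesh$nodes, mesh$elems, mesh$active, mesh$mat,
                          setup$props, mass, setup$fixed, mesh$nr, mesh$nz,
                          probe$radius, mesh$spec$depth, v_eff,
                          setup$knode, dt, as.integer(nsteps),
                          as.integer(record_every), config$epsp_max,
                          config$damping, matrix(0, ne, 16), matrix(0, ne, 4),
                          setup$cand_rad, ramp_time)
  flags <- character(0)
  if (isTRUE(res$unstable))
    flags <- "explicit instability detected (runaway displacement); aborted"

  w <- config$filter_window
  fsm <- as.numeric(stats::filter(res$force, rep(1 / w, w), sides = 2))
  naw <- is.na(fsm)
  fsm[naw] <- res$force[naw]
  mesh$active <- res$active
  st <- list(u = res$u, sig = res$sig, epsp = res$epsp, active = res$active)
  out <- .new_result(mesh, probe, config,
                     times = res$time / config$time_scale,
                     depths = res$depth, forces = fsm,
                     snapshots = list(),
                     eroded = list(step = res$eroded_step, elem = res$eroded_elem),
                     flags = flags, state = st)
  out$curve_raw <- force_deformation_curve(res$time / config$time_scale,
                                           res$depth, pmax(res$force, 0),
                                           source = "simulated")
  out$dt <- dt
  out
}
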