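#' Axisymmetric sample domain specification
#'
#' The modelled sample is an axisymmetric cylinder of \code{radius} x
#' \code{depth} (the local cross-section under the probe), with a thin skin
#' band of solid elements at the top surface over flesh, punctured on the
#' axis by a rigid flat-end probe.
#'
#' @param radius Sample radius (mm). Default 15.
#' @param depth Sample depth (mm). Default 20.
#' @param skin_thickness Skin layer thickness (mm). Default 1.
#' @param probe_radius Flat-punch radius (mm). Default 1 (2 mm diameter probe).
#' @return Object of class \code{domain_spec}.
#' @export
domain_spec <- function(radius = 15, depth = 20, skin_thickness = 1,
                        probe_radius = 1) {
  if (any(!is.finite(c(radius, depth, skin_thickness, probe_radius))))
    stop("domain_spec: all dimensions must be finite", call. = FALSE)
  if (skin_thickness <= 0 || skin_thickness >= depth)
    stop("domain_spec: require 0 < skin_thickness < depth", call. = FALSE)
  if (probe_radius <= 0 || probe_radius >= radius)
    stop("domain_spec: require 0 < probe_radius < radius", call. = FALSE)
  structure(list(radius = radius, depth = depth,
                 skin_thickness = skin_thickness, probe_radius = probe_radius),
            class = "domain_spec")
}

# Graded 1D spacing: sizes start at h0 and grow geometrically (factor 1.3)
# up to hmax; the remainder becomes its own cell (or is merged into the last
# one when small), so no cell ever exceeds hmax and the lengths sum to L
# exactly.
.graded_spacing <- function(L, h0, hmax, grow = 1.3) {
  if (L <= 0) return(numeric(0))
  if (L <= h0 * 1.5) return(rep(L / max(1, round(L / h0)), max(1, round(L / h0))))
  sizes <- numeric(0)
  h <- h0
  total <- 0
  while (total + h < L - 1e-12) {
    sizes <- c(sizes, h)
    total <- total + h
    h <- min(h * grow, hmax)
  }
  rem <- L - total
  last <- sizes[length(sizes)]
  if (rem >= 0.5 * h0 || last + rem > hmax) {
    sizes <- c(sizes, rem)
  } else {
    sizes[length(sizes)] <- last + rem
  }
  sizes
}

#' Build a graded structured quadrilateral mesh of the layered sample
#'
#' Structured axisymmetric grid with element edge length at most
#' \code{target_h} under the punch footprint (r <= 2 probe radii) and in the
#' skin band (at least two element rows through the skin thickness), grading
#' geometrically up to \code{refinement_ratio} times the finest spacing
#' towards the far boundaries. The skin/flesh interface is mesh-conforming:
#' a grid line lies exactly at \code{depth - skin_thickness}.
#'
#' @param spec A \code{\link{domain_spec}}.
#' @param target_h Target element edge length under the probe (mm).
#' @param refinement_ratio Maximum ratio of coarsest to finest spacing
#'   (1 = uniform mesh).
#' @return Object of class \code{puncture_mesh} with fields \code{nodes}
#'   (n x 2 matrix of (r, z) in mm), \code{elems} (ne x 4 counter-clockwise
#'   connectivity), \code{mat} (1 = skin, 2 = flesh), \code{active} (logical),
#'   and the generating \code{spec}.
#' @export
build_mesh <- function(spec, target_h = 0.5, refinement_ratio = 4) {
  stopifnot(inherits(spec, "domain_spec"))
  if (target_h <= 0) stop("build_mesh: target_h must be positive", call. = FALSE)
  if (refinement_ratio < 1)
    stop("build_mesh: refinement_ratio must be >= 1", call. = FALSE)
  if (target_h > spec$skin_thickness)
    stop("infeasible-mesh: target_h exceeds the skin thickness (need >= 2 rows through the skin)",
         call. = FALSE)

  # fine spacings under the punch and through the skin
  r_fine <- min(2 * spec$probe_radius, spec$radius)
  n_rf <- max(2L, ceiling(r_fine / target_h))
  h_r <- r_fine / n_rf
  n_skin <- max(2L, ceiling(spec$skin_thickness / target_h))
  h_skin <- spec$skin_thickness / n_skin
  hmax <- refinement_ratio * min(h_r, h_skin)

  r_breaks <- c(seq(0, r_fine, by = h_r),
                r_fine + cumsum(.graded_spacing(spec$radius - r_fine, h_r, hmax)))
  r_breaks[length(r_breaks)] <- spec$radius

  z_top <- spec$depth
  z_if <- spec$depth - spec$skin_thickness
  z_skin <- seq(z_if, z_top, by = h_skin)
  z_below <- z_if - cumsum(.graded_spacing(z_if, h_skin, hmax))
  z_below[length(z_below)] <- 0
  z_breaks <- c(rev(z_below), z_skin)

  nr <- length(r_breaks) - 1L
  nz <- length(z_breaks) - 1L
  nodes <- cbind(r = rep(r_breaks, nz + 1L),
                 z = rep(z_breaks, each = nr + 1L))
  eli <- rep(seq_len(nr), nz)
  elj <- rep(seq_len(nz), each = nr)
  n1 <- (elj - 1L) * (nr + 1L) + eli
  elems <- cbind(n1, n1 + 1L, n1 + nr + 2L, n1 + nr + 1L)
  cz <- (z_breaks[elj] + z_breaks[elj + 1L]) / 2
  mat <- ifelse(cz > z_if, 1L, 2L)

  structure(list(nodes = nodes, elems = elems, mat = mat,
                 active = rep(TRUE, nrow(elems)),
                 nr = nr, nz = nz, r_breaks = r_breaks, z_breaks = z_breaks,
                 spec = spec),
            class = "puncture_mesh")
}

#' @exportS3Method base::print
print.puncture_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric layered mesh: %d nodes, %d quad elements (%d skin, %d flesh)\n",
              nrow(x$nodes), nrow(x$elems), sum(x$mat == 1L), sum(x$mat == 2L)))
  cat(sprintf("  domain %g x %g mm, skin %g mm, %d active elements\n",
              x$spec$radius, x$spec$depth, x$spec$skin_thickness, sum(x$active)))
  invisible(x)
}

# signed area of each quad (shoelace); positive for counter-clockwise
.element_areas <- function(mesh) {
  r <- matrix(mesh$nodes[t(mesh$elems), 1], ncol = 4, byrow = TRUE)
  z <- matrix(mesh$nodes[t(mesh$elems), 2], ncol = 4, byrow = TRUE)
  0.5 * ((r[, 1] * z[, 2] - r[, 2] * z[, 1]) +
         (r[, 2] * z[, 3] - r[, 3] * z[, 2]) +
         (r[, 3] * z[, 4] - r[, 4] * z[, 3]) +
         (r[, 4] * z[, 1] - r[, 1] * z[, 4]))
}

#' Element quality summary of a mesh
#'
#' Edge aspect ratios and corner (scaled) Jacobians per element. Inverted
#' elements are reported with non-positive Jacobian, not raised as errors.
#'
#' @param mesh A \code{\link{build_mesh}} result.
#' @return List with per-element vectors \code{aspect} and
#'   \code{min_scaled_jacobian}, summary fields \code{max_aspect},
#'   \code{min_jacobian}, and indices of \code{inverted} elements.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "puncture_mesh"))
  ne <- nrow(mesh$elems)
  r <- matrix(mesh$nodes[t(mesh$elems), 1], ncol = 4, byrow = TRUE)
  z <- matrix(mesh$nodes[t(mesh$elems), 2], ncol = 4, byrow = TRUE)
  nxt <- c(2, 3, 4, 1)
  er <- r[, nxt] - r
  ez <- z[, nxt] - z
  elen <- sqrt(er^2 + ez^2)
  aspect <- apply(elen, 1, max) / apply(elen, 1, min)
  # scaled Jacobian at each corner: cross product of the two incident edges
  prv <- c(4, 1, 2, 3)
  sj <- matrix(NA_real_, ne, 4)
  for (k in 1:4) {
    ar <- er[, k]; az <- ez[, k]
    br <- -er[, prv[k]]; bz <- -ez[, prv[k]]
    cross <- ar * bz - az * br
    sj[, k] <- cross / (elen[, k] * elen[, prv[k]])
  }
  minsj <- apply(sj, 1, min)
  list(aspect = aspect, min_scaled_jacobian = minsj,
       max_aspect = max(aspect[mesh$active]),
       min_jacobian = min(minsj[mesh$active]),
       inverted = which(minsj <= 0))
}

#' Write a mesh (with optional fields) as a legacy ASCII VTK file
#'
#' Unstructured-grid output with the axisymmetric (r, z) plane embedded at
#' y = 0. Cell data always include the material tag and active flag;
#' further point/cell fields may be supplied.
#'
#' @param mesh A \code{\link{build_mesh}} result.
#' @param file Output path (conventionally .vtk).
#' @param point_data Named list of per-node numeric vectors or n x 2
#'   matrices (written as 3-vectors with zero y).
#' @param cell_data Named list of per-element numeric vectors.
#' @return The file path, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "puncture_mesh"))
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "axisymmetric puncture mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n))
  wl(sprintf("%.9g 0 %.9g", mesh$nodes[, 1], mesh$nodes[, 2]))
  wl(sprintf("CELLS %d %d", ne, 5L * ne))
  wl(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
             mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L))
  wl(sprintf("CELL_TYPES %d", ne))
  wl(rep("9", ne))  # VTK_QUAD
  cell_data <- c(list(material = as.numeric(mesh$mat),
                      active = as.numeric(mesh$active)), cell_data)
  wl(sprintf("CELL_DATA %d", ne))
  for (nm in names(cell_data)) {
    wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    wl(sprintf("%.9g", as.numeric(cell_data[[nm]])))
  }
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 2) {
        wl(sprintf("VECTORS %s double", nm))
        wl(sprintf("%.9g 0 %.9g", v[, 1], v[, 2]))
      } else {
        wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        wl(sprintf("%.9g", as.numeric(v)))
      }
    }
  }
  invisible(file)
}
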