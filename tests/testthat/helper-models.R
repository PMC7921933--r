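# Shared fixtures and small oracles for the test suite. Everything is built
# in code; no binary fixtures.

# drive one integration point along a uniaxial *stress* path (axial strain
# prescribed, lateral strain iterated so the radial stress vanishes); the
# independent oracle for the radial-return map is the uniaxial bilinear law
uniaxial_trace <- function(p, eps_axial, lat_tol = 1e-12) {
  state <- list(sig = numeric(4), epsp = 0)
  eps_prev <- 0
  lat_prev <- 0
  sig_out <- numeric(length(eps_axial))
  for (k in seq_along(eps_axial)) {
    da <- eps_axial[k] - eps_prev
    resid <- function(dl) {
      s <- radial_return(c(dl, da, dl, 0), state, p)
      s$sig[1]
    }
    # bracket the lateral strain increment
    span <- max(abs(da), 1e-8)
    lo <- -2 * span; hi <- 2 * span
    while (resid(lo) * resid(hi) > 0) { lo <- 2 * lo; hi <- 2 * hi }
    dl <- stats::uniroot(resid, c(lo, hi), tol = lat_tol)$root
    upd <- radial_return(c(dl, da, dl, 0), state, p)
    state$sig <- upd$sig
    state$epsp <- upd$epsp
    sig_out[k] <- upd$sig[2]
    eps_prev <- eps_axial[k]
    lat_prev <- lat_prev + dl
  }
  sig_out
}

# elastic strain energy of a committed state, integrated over the active
# elements with the same 2x2 Gauss rule as the solver (independent R-side
# quadrature; complementary energy density from the stress tensor)
strain_energy <- function(mesh, state, materials) {
  gp <- 1 / sqrt(3)
  xi <- c(-gp, gp, gp, -gp); eta <- c(-gp, -gp, gp, gp)
  U <- 0
  for (e in which(state$active)) {
    nd <- mesh$elems[e, ]
    xr <- mesh$nodes[nd, 1]; xz <- mesh$nodes[nd, 2]
    m <- if (mesh$mat[e] == 1L) materials$skin else materials$flesh
    for (g in 1:4) {
      x <- xi[g]; et <- eta[g]
      N <- 0.25 * c((1 - x) * (1 - et), (1 + x) * (1 - et),
                    (1 + x) * (1 + et), (1 - x) * (1 + et))
      dNx <- 0.25 * c(-(1 - et), (1 - et), (1 + et), -(1 + et))
      dNe <- 0.25 * c(-(1 - x), -(1 + x), (1 + x), (1 - x))
      J <- rbind(c(sum(dNx * xr), sum(dNx * xz)),
                 c(sum(dNe * xr), sum(dNe * xz)))
      detJ <- det(J)
      r <- sum(N * xr)
      w <- 2 * pi * r * detJ
      s <- state$sig[e, (4 * g - 3):(4 * g)]
      tr <- s[1] + s[2] + s[3]
      ss <- sum(s[1:3]^2) + 2 * s[4]^2
      U <- U + w * ((1 + m$nu) / (2 * m$E) * ss - m$nu / (2 * m$E) * tr^2)
    }
  }
  U
}

# external work done by the punch: trapezoid on the force curve, including
# the leading segment from first contact at zero depth
external_work <- function(curve) {
  f <- c(0, curve$forces); d <- c(0, curve$depths)
  sum(0.5 * (f[-1] + f[-length(f)]) * diff(d))
}

# the full calibrated validation study is expensive; run it once and share
.validation_cache <- new.env(parent = emptyenv())
cached_validation <- function() {
  if (is.null(.validation_cache$report))
    .validation_cache$report <- run_validation(default_config())
  .validation_cache$report
}
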