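// Element-level kernels for the axisymmetric puncture solver:
//  - J2 radial-return stress update with linear isotropic hardening
//  - 4-node axisymmetric quad with mean-dilatation B-bar (selective reduced
//    integration of the volumetric term), internal force + consistent tangent
//  - structured-grid contact-candidate / attachment bookkeeping for the
//    eroding rigid flat-punch contact
//  - central-difference explicit integrator
//
// Unit system: mm - N - MPa - s, density in tonne/mm^3.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GP = 0.5773502691896257;  // 1/sqrt(3)

// Voigt order [rr, zz, tt, rz], engineering shear strain gamma_rz.
// Radial return from committed stress/epsp with total strain increment deps.
// Returns plastic multiplier; updates sig (4) and epsp in place.
static double radial_return_point(double* sig, const double* deps, double& epsp,
                                  double E, double nu, double sigy, double H,
                                  double& vm_out) {
  const double G = E / (2.0 * (1.0 + nu));
  const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double tr = deps[0] + deps[1] + deps[2];
  double st[4];
  st[0] = sig[0] + lam * tr + 2.0 * G * deps[0];
  st[1] = sig[1] + lam * tr + 2.0 * G * deps[1];
  st[2] = sig[2] + lam * tr + 2.0 * G * deps[2];
  st[3] = sig[3] + G * deps[3];
  const double p = (st[0] + st[1] + st[2]) / 3.0;
  double s[4] = { st[0] - p, st[1] - p, st[2] - p, st[3] };
  const double snorm2 = s[0]*s[0] + s[1]*s[1] + s[2]*s[2] + 2.0*s[3]*s[3];
  const double q = std::sqrt(1.5 * snorm2);
  const double f = q - (sigy + H * epsp);
  double dgamma = 0.0;
  if (f > 0.0 && q > 0.0) {
    dgamma = f / (3.0 * G + H);
    const double fac = 3.0 * G * dgamma / q;
    for (int c = 0; c < 4; ++c) st[c] -= fac * s[c];
    epsp += dgamma;
  }
  for (int c = 0; c < 4; ++c) sig[c] = st[c];
  const double p2 = (sig[0] + sig[1] + sig[2]) / 3.0;
  double d0 = sig[0]-p2, d1 = sig[1]-p2, d2 = sig[2]-p2, d3 = sig[3];
  vm_out = std::sqrt(1.5 * (d0*d0 + d1*d1 + d2*d2 + 2.0*d3*d3));
  return dgamma;
}

// [[Rcpp::export]]
List cpp_radial_return(NumericVector sig_old, NumericVector deps, double epsp,
                       double E, double nu, double sigy, double H) {
  if (sig_old.size() != 4 || deps.size() != 4)
    stop("cpp_radial_return: stress and strain increment must have 4 components");
  for (int c = 0; c < 4; ++c)
    if (!R_finite(sig_old[c]) || !R_finite(deps[c]))
      stop("numerical-state: non-finite stress or strain increment");
  double sig[4] = { sig_old[0], sig_old[1], sig_old[2], sig_old[3] };
  double de[4] = { deps[0], deps[1], deps[2], deps[3] };
  double ep = epsp, vm = 0.0;
  double dg = radial_return_point(sig, de, ep, E, nu, sigy, H, vm);
  return List::create(_["sig"] = NumericVector::create(sig[0], sig[1], sig[2], sig[3]),
                      _["epsp"] = ep, _["dgamma"] = dg, _["vm"] = vm);
}

// consistent elastoplastic tangent (Simo & Hughes), Voigt engineering shear
static void tangent_point(double D[4][4], const double* sig_committed,
                          const double* deps, double epsp_committed,
                          double E, double nu, double sigy, double H) {
  const double G = E / (2.0 * (1.0 + nu));
  const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  const double K = lam + 2.0 * G / 3.0;
  const double tr = deps[0] + deps[1] + deps[2];
  double st[4];
  st[0] = sig_committed[0] + lam * tr + 2.0 * G * deps[0];
  st[1] = sig_committed[1] + lam * tr + 2.0 * G * deps[1];
  st[2] = sig_committed[2] + lam * tr + 2.0 * G * deps[2];
  st[3] = sig_committed[3] + G * deps[3];
  const double p = (st[0] + st[1] + st[2]) / 3.0;
  double s[4] = { st[0] - p, st[1] - p, st[2] - p, st[3] };
  const double snorm = std::sqrt(s[0]*s[0] + s[1]*s[1] + s[2]*s[2] + 2.0*s[3]*s[3]);
  const double q = std::sqrt(1.5) * snorm;
  const double f = q - (sigy + H * epsp_committed);

  // deviatoric projector in Voigt (engineering shear)
  static const double Id[4][4] = {
    { 2.0/3.0, -1.0/3.0, -1.0/3.0, 0.0 },
    {-1.0/3.0,  2.0/3.0, -1.0/3.0, 0.0 },
    {-1.0/3.0, -1.0/3.0,  2.0/3.0, 0.0 },
    { 0.0,      0.0,      0.0,     0.5 } };
  if (f <= 0.0 || q <= 0.0) {
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double one = (a < 3 && b < 3) ? 1.0 : 0.0;
        D[a][b] = K * one + 2.0 * G * Id[a][b];
      }
    return;
  }
  const double dgamma = f / (3.0 * G + H);
  const double theta = 1.0 - 3.0 * G * dgamma / q;
  const double thetabar = 3.0 * G / (3.0 * G + H) - 3.0 * G * dgamma / q;
  double n[4] = { s[0]/snorm, s[1]/snorm, s[2]/snorm, s[3]/snorm };
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      double one = (a < 3 && b < 3) ? 1.0 : 0.0;
      D[a][b] = K * one + 2.0 * G * theta * Id[a][b]
                - 2.0 * G * thetabar * n[a] * n[b];
    }
}

struct GpData {
  double B[4][8];     // B-bar strain-displacement
  double w;           // 2*pi*r*detJ*wgp
};

// Build B-bar data for one element; returns false on non-positive Jacobian.
static bool element_gp_data(const double* xr, const double* xz, GpData gp[4]) {
  const double xi[4] = { -GP,  GP,  GP, -GP };
  const double eta[4] = { -GP, -GP,  GP,  GP };
  double bvol[4][8];      // volumetric row per gp
  double bbar[8] = {0,0,0,0,0,0,0,0};
  double wtot = 0.0;
  for (int g = 0; g < 4; ++g) {
    const double x = xi[g], e = eta[g];
    double N[4]  = { 0.25*(1-x)*(1-e), 0.25*(1+x)*(1-e),
                     0.25*(1+x)*(1+e), 0.25*(1-x)*(1+e) };
    double dNx[4] = { -0.25*(1-e), 0.25*(1-e), 0.25*(1+e), -0.25*(1+e) };
    double dNe[4] = { -0.25*(1-x), -0.25*(1+x), 0.25*(1+x), 0.25*(1-x) };
    double j11=0, j12=0, j21=0, j22=0;
    for (int a = 0; a < 4; ++a) {
      j11 += dNx[a]*xr[a]; j12 += dNx[a]*xz[a];
      j21 += dNe[a]*xr[a]; j22 += dNe[a]*xz[a];
    }
    const double det = j11*j22 - j12*j21;
    if (det <= 0.0) return false;
    double dNr[4], dNz[4];
    for (int a = 0; a < 4; ++a) {
      dNr[a] = ( j22*dNx[a] - j12*dNe[a]) / det;
      dNz[a] = (-j21*dNx[a] + j11*dNe[a]) / det;
    }
    double r = 0.0;
    for (int a = 0; a < 4; ++a) r += N[a]*xr[a];
    const double w = 2.0 * M_PI * r * det;  // gauss weight 1
    gp[g].w = w;
    for (int a = 0; a < 4; ++a) {
      // standard axisymmetric B
      gp[g].B[0][2*a]   = dNr[a];   gp[g].B[0][2*a+1] = 0.0;
      gp[g].B[1][2*a]   = 0.0;      gp[g].B[1][2*a+1] = dNz[a];
      gp[g].B[2][2*a]   = N[a]/r;   gp[g].B[2][2*a+1] = 0.0;
      gp[g].B[3][2*a]   = dNz[a];   gp[g].B[3][2*a+1] = dNr[a];
      bvol[g][2*a]   = dNr[a] + N[a]/r;
      bvol[g][2*a+1] = dNz[a];
    }
    for (int c = 0; c < 8; ++c) bbar[c] += w * bvol[g][c];
    wtot += w;
  }
  for (int c = 0; c < 8; ++c) bbar[c] /= wtot;
  // replace the pointwise volumetric part by the element mean (B-bar)
  for (int g = 0; g < 4; ++g)
    for (int c = 0; c < 8; ++c) {
      const double corr = (bbar[c] - bvol[g][c]) / 3.0;
      gp[g].B[0][c] += corr;
      gp[g].B[1][c] += corr;
      gp[g].B[2][c] += corr;
    }
  return true;
}

// Assemble internal force, optional consistent tangent triplets, and the
// trial (uncommitted) stress state for displacement u given committed
// state (sig0, epsp0) at displacement u0.
// props: one row per material id, columns E, nu, sigy, H.
// sig0: ne x 16 (gauss-point-major), epsp0: ne x 4.
// [[Rcpp::export]]
List cpp_assemble(NumericMatrix nodes, IntegerMatrix elems, LogicalVector active,
                  IntegerVector mat, NumericMatrix props,
                  NumericVector u, NumericVector u0,
                  NumericMatrix sig0, NumericMatrix epsp0, bool tangent) {
  const int ne = elems.nrow();
  const int ndof = nodes.nrow() * 2;
  NumericVector fint(ndof);
  NumericMatrix sig_new(ne, 16), epsp_new(ne, 4), vm(ne, 4);
  NumericVector epsp_el_max(ne);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  if (tangent) { ti.reserve(ne*64); tj.reserve(ne*64); tv.reserve(ne*64); }

  for (int e = 0; e < ne; ++e) {
    if (!active[e]) continue;
    int nd[4];
    double xr[4], xz[4], ue[8], due[8];
    for (int a = 0; a < 4; ++a) {
      nd[a] = elems(e, a) - 1;
      xr[a] = nodes(nd[a], 0);
      xz[a] = nodes(nd[a], 1);
      ue[2*a]   = u[2*nd[a]];
      ue[2*a+1] = u[2*nd[a]+1];
      due[2*a]   = ue[2*a]   - u0[2*nd[a]];
      due[2*a+1] = ue[2*a+1] - u0[2*nd[a]+1];
    }
    GpData gp[4];
    if (!element_gp_data(xr, xz, gp))
      stop("cpp_assemble: non-positive Jacobian in element %d", e + 1);
    const int m = mat[e] - 1;
    const double E = props(m, 0), nu = props(m, 1), sy = props(m, 2), H = props(m, 3);
    double Ke[8][8];
    if (tangent) for (int a = 0; a < 8; ++a) for (int b = 0; b < 8; ++b) Ke[a][b] = 0.0;
    double fe[8] = {0,0,0,0,0,0,0,0};
    double emax = 0.0;
    for (int g = 0; g < 4; ++g) {
      double deps[4] = {0,0,0,0};
      for (int c = 0; c < 8; ++c)
        for (int k = 0; k < 4; ++k) deps[k] += gp[g].B[k][c] * due[c];
      double sg[4];
      for (int c = 0; c < 4; ++c) sg[c] = sig0(e, 4*g + c);
      double ep = epsp0(e, g), vmp = 0.0;
      radial_return_point(sg, deps, ep, E, nu, sy, H, vmp);
      for (int c = 0; c < 4; ++c) sig_new(e, 4*g + c) = sg[c];
      epsp_new(e, g) = ep;
      vm(e, g) = vmp;
      if (ep > emax) emax = ep;
      for (int c = 0; c < 8; ++c) {
        double s = 0.0;
        for (int k = 0; k < 4; ++k) s += gp[g].B[k][c] * sg[k];
        fe[c] += s * gp[g].w;
      }
      if (tangent) {
        double sg0[4];
        for (int c = 0; c < 4; ++c) sg0[c] = sig0(e, 4*g + c);
        double D[4][4];
        tangent_point(D, sg0, deps, epsp0(e, g), E, nu, sy, H);
        double DB[4][8];
        for (int k = 0; k < 4; ++k)
          for (int c = 0; c < 8; ++c) {
            double s = 0.0;
            for (int l = 0; l < 4; ++l) s += D[k][l] * gp[g].B[l][c];
            DB[k][c] = s;
          }
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            double s = 0.0;
            for (int k = 0; k < 4; ++k) s += gp[g].B[k][a] * DB[k][b];
            Ke[a][b] += s * gp[g].w;
          }
      }
    }
    epsp_el_max[e] = emax;
    int edof[8];
    for (int a = 0; a < 4; ++a) { edof[2*a] = 2*nd[a]; edof[2*a+1] = 2*nd[a]+1; }
    for (int a = 0; a < 8; ++a) fint[edof[a]] += fe[a];
    if (tangent)
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b) {
          ti.push_back(edof[a] + 1);
          tj.push_back(edof[b] + 1);
          tv.push_back(Ke[a][b]);
        }
  }
  List out = List::create(_["fint"] = fint, _["sig"] = sig_new,
                          _["epsp"] = epsp_new, _["vm"] = vm,
                          _["epsp_el_max"] = epsp_el_max);
  if (tangent) {
    out["ki"] = IntegerVector(ti.begin(), ti.end());
    out["kj"] = IntegerVector(tj.begin(), tj.end());
    out["kv"] = NumericVector(tv.begin(), tv.end());
  }
  return out;
}

// Structured-grid bookkeeping. Elements are column-major in (i = 1..nr,
// j = 1..nz), element index e = (j-1)*nr + i; nodes (i = 1..nr+1, j = 1..nz+1),
// node index = (j-1)*(nr+1) + i.
// A node is a top-contact candidate when no active element sits above it in
// either adjacent element column (the punch can reach it) and it lies on the
// top face of an active element. This realises eroding contact: nodes exposed
// by element deletion become candidates.
// [[Rcpp::export]]
List cpp_surface_info(LogicalVector active, int nr, int nz) {
  std::vector<int> topAct(nr + 2, 0);  // 1-based element columns
  for (int i = 1; i <= nr; ++i)
    for (int j = nz; j >= 1; --j)
      if (active[(j - 1) * nr + i - 1]) { topAct[i] = j; break; }
  const int nn = (nr + 1) * (nz + 1);
  LogicalVector candidate(nn), attached(nn);
  for (int jn = 1; jn <= nz + 1; ++jn)
    for (int in = 1; in <= nr + 1; ++in) {
      const int node = (jn - 1) * (nr + 1) + in - 1;
      bool att = false, blocked = false, topface = false;
      for (int c = in - 1; c <= in; ++c) {
        if (c < 1 || c > nr) continue;
        for (int j = jn - 1; j <= jn; ++j) {
          if (j < 1 || j > nz) continue;
          if (active[(j - 1) * nr + c - 1]) att = true;
        }
        if (topAct[c] >= jn) blocked = true;
        if (jn >= 2 && topAct[c] == jn - 1) topface = true;
      }
      attached[node] = att;
      candidate[node] = att && !blocked && topface;
    }
  return List::create(_["candidate"] = candidate, _["attached"] = attached);
}

// Central-difference explicit dynamics with eroding flat-punch penalty
// contact. props rows per material: E, nu, sigy, H, rho (tonne/mm^3).
// Punch face starts at z_top and advances at `velocity` (mm/s, already
// time-scaled by the caller). Mass-proportional damping coefficient `damp`
// (1/s). Records every `record_every` steps. Erosion is checked every step.
// [[Rcpp::export]]
List cpp_explicit_run(NumericMatrix nodes, IntegerMatrix elems, LogicalVector active_,
                      IntegerVector mat, NumericMatrix props,
                      NumericVector mass, LogicalVector fixed_dof,
                      int nr, int nz,
                      double probe_radius, double z_top, double velocity,
                      NumericVector knode, double dt, int nsteps,
                      int record_every, double epsp_max, double damp,
                      NumericMatrix sig_init, NumericMatrix epsp_init,
                      LogicalVector cand_rad, double ramp_time) {
  const int ne = elems.nrow();
  const int nn = nodes.nrow();
  const int ndof = 2 * nn;
  LogicalVector active = clone(active_);
  NumericMatrix sig = clone(sig_init);
  NumericMatrix epsp = clone(epsp_init);
  NumericVector u(ndof), v(ndof), u_prev(ndof);
  std::vector<double> rec_t, rec_d, rec_f;
  std::vector<int> eroded_step;
  std::vector<int> eroded_elem;
  bool unstable = false;

  List surf = cpp_surface_info(active, nr, nz);
  LogicalVector candidate = surf["candidate"];
  LogicalVector attached = surf["attached"];

  const double domain_span = z_top * 4.0 + 10.0;
  double t = 0.0;
  for (int step = 0; step < nsteps; ++step) {
    t += dt;
    // smooth-start ramp of the punch motion suppresses the impact transient
    const double depth = (ramp_time > 0.0 && t < ramp_time)
      ? velocity * t * t / (2.0 * ramp_time)
      : velocity * (t - ramp_time / 2.0);
    const double z_face = z_top - depth;

    // internal forces + stress update (committed every step)
    NumericVector fint(ndof);
    bool any_eroded = false;
    for (int e = 0; e < ne; ++e) {
      if (!active[e]) continue;
      int nd[4];
      double xr[4], xz[4], due[8];
      for (int a = 0; a < 4; ++a) {
        nd[a] = elems(e, a) - 1;
        xr[a] = nodes(nd[a], 0);
        xz[a] = nodes(nd[a], 1);
        due[2*a]   = u[2*nd[a]]   - u_prev[2*nd[a]];
        due[2*a+1] = u[2*nd[a]+1] - u_prev[2*nd[a]+1];
      }
      GpData gp[4];
      if (!element_gp_data(xr, xz, gp)) { active[e] = false; continue; }
      const int m = mat[e] - 1;
      const double E = props(m, 0), nu = props(m, 1), sy = props(m, 2), H = props(m, 3);
      double fe[8] = {0,0,0,0,0,0,0,0};
      double emax = 0.0;
      for (int g = 0; g < 4; ++g) {
        double deps[4] = {0,0,0,0};
        for (int c = 0; c < 8; ++c)
          for (int k = 0; k < 4; ++k) deps[k] += gp[g].B[k][c] * due[c];
        double sg[4];
        for (int c = 0; c < 4; ++c) sg[c] = sig(e, 4*g + c);
        double ep = epsp(e, g), vmp = 0.0;
        radial_return_point(sg, deps, ep, E, nu, sy, H, vmp);
        for (int c = 0; c < 4; ++c) sig(e, 4*g + c) = sg[c];
        epsp(e, g) = ep;
        if (ep > emax) emax = ep;
        for (int c = 0; c < 8; ++c) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += gp[g].B[k][c] * sg[k];
          fe[c] += s * gp[g].w;
        }
      }
      for (int a = 0; a < 4; ++a) {
        fint[2*nd[a]]   += fe[2*a];
        fint[2*nd[a]+1] += fe[2*a+1];
      }
      if (emax >= epsp_max) {
        active[e] = false;
        for (int c = 0; c < 16; ++c) sig(e, c) = 0.0;
        eroded_step.push_back(step + 1);
        eroded_elem.push_back(e + 1);
        any_eroded = true;
      }
    }
    if (any_eroded) {
      surf = cpp_surface_info(active, nr, nz);
      candidate = surf["candidate"];
      attached = surf["attached"];
    }

    // contact penalty forces
    double fcontact_total = 0.0;
    NumericVector fc(ndof);
    for (int n = 0; n < nn; ++n) {
      if (!cand_rad[n] || !candidate[n]) continue;
      const double zc = nodes(n, 1) + u[2*n + 1];
      const double pen = zc - z_face;
      if (pen > 0.0) {
        const double f = knode[n] * pen;
        fc[2*n + 1] -= f;
        fcontact_total += f;
      }
    }

    u_prev = clone(u);
    double ke = 0.0;
    for (int d = 0; d < ndof; ++d) {
      // orphan nodes (all incident elements eroded) are frozen
      if (fixed_dof[d] || mass[d] <= 0.0 || !attached[d / 2]) { v[d] = 0.0; continue; }
      const double a = (fc[d] - fint[d]) / mass[d] - damp * v[d];
      v[d] += dt * a;
      u[d] += dt * v[d];
      ke += 0.5 * mass[d] * v[d] * v[d];
      if (std::fabs(u[d]) > domain_span) unstable = true;
    }
    if ((step + 1) % record_every == 0 || step == nsteps - 1) {
      rec_t.push_back(t);
      rec_d.push_back(depth);
      rec_f.push_back(fcontact_total);
    }
    if (unstable) break;
  }
  return List::create(_["time"] = NumericVector(rec_t.begin(), rec_t.end()),
                      _["depth"] = NumericVector(rec_d.begin(), rec_d.end()),
                      _["force"] = NumericVector(rec_f.begin(), rec_f.end()),
                      _["active"] = active, _["sig"] = sig, _["epsp"] = epsp,
                      _["u"] = u,
                      _["eroded_step"] = IntegerVector(eroded_step.begin(), eroded_step.end()),
                      _["eroded_elem"] = IntegerVector(eroded_elem.begin(), eroded_elem.end()),
                      _["unstable"] = unstable);
}
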