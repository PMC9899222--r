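// Steady incompressible room-airflow solver: SIMPLE pressure-velocity
// coupling on a uniform staggered Cartesian grid, hybrid/upwind advection,
// constant-effective-viscosity or standard k-epsilon closure with
// log-law wall functions.  Boundary tags per face: 0 = no-slip wall,
// 1 = velocity inlet (uniform normal speed uin, into the domain),
// 2 = outflow (zero-gradient, globally mass-corrected), 3 = free slip,
// 4 = moving lid (no-slip wall translating in +x at lid_u; verification
// presets only).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const double KAPPA = 0.41, EWALL = 9.793;
const double CMU = 0.09, C1E = 1.44, C2E = 1.92, SIGK = 1.0, SIGE = 1.3;

struct Mesh {
  int nx, ny, nz;
  double dx, dy, dz, Ax, Ay, Az, vol;
  inline int cell(int i, int j, int k) const { return i + nx * (j + ny * k); }
  inline int iu(int i, int j, int k) const { return i + (nx + 1) * (j + ny * k); }
  inline int iv(int i, int j, int k) const { return i + nx * (j + (ny + 1) * k); }
  inline int iw(int i, int j, int k) const { return i + nx * (j + ny * k); }
  inline int ncell() const { return nx * ny * nz; }
  inline int nu() const { return (nx + 1) * ny * nz; }
  inline int nv() const { return nx * (ny + 1) * nz; }
  inline int nw() const { return nx * ny * (nz + 1); }
};

inline bool dirichlet_tag(int t) { return t == 0 || t == 1 || t == 4; }

// Combined tangential-boundary tag for a face control volume straddling two
// cells: no-slip dominates, then inlet/lid, else outflow/slip (zero-gradient).
inline int combine_tags(int t1, int t2) {
  if (dirichlet_tag(t1)) return t1;
  if (dirichlet_tag(t2)) return t2;
  return t1;
}

inline double hybrid_coef(double D, double F, int scheme) {
  // Coefficient of the neighbour on the far side of a face with outward
  // mass flux F (positive leaving the CV) and conductance D.
  if (scheme == 0) return D + std::max(-F, 0.0); // first-order upwind
  return std::max(std::max(-F, D - 0.5 * F), 0.0); // hybrid
}

struct State {
  Mesh m;
  IntegerMatrix bx0, bx1, by0, by1, bz0, bz1;
  std::vector<double> u, v, w, p, tk, te, mut;
  std::vector<double> du, dv, dw;      // d = A / aP for pressure correction
  std::vector<double> aE, aW, aN, aS, aT, aB, aP, bb; // scratch coefficients
  double uin, lid_u, rho, mu, nu_eff, kin, epsin;
  int closure, scheme;
  double alpha_u, alpha_p, alpha_t;

  double mueff_cell(int c) const {
    if (closure == 0) return rho * nu_eff;
    return mu + mut[c];
  }
};

// Fill fixed boundary-normal velocities (walls, slip, inlet). Outflow faces
// are handled by outlet_update().
void set_boundary_normals(State& S) {
  const Mesh& m = S.m;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j) {
      int t0 = S.bx0(j, k), t1 = S.bx1(j, k);
      if (t0 != 2) S.u[m.iu(0, j, k)] = (t0 == 1) ? S.uin : 0.0;
      if (t1 != 2) S.u[m.iu(m.nx, j, k)] = (t1 == 1) ? -S.uin : 0.0;
    }
  for (int k = 0; k < m.nz; ++k)
    for (int i = 0; i < m.nx; ++i) {
      int t0 = S.by0(i, k), t1 = S.by1(i, k);
      if (t0 != 2) S.v[m.iv(i, 0, k)] = (t0 == 1) ? S.uin : 0.0;
      if (t1 != 2) S.v[m.iv(i, m.ny, k)] = (t1 == 1) ? -S.uin : 0.0;
    }
  for (int j = 0; j < m.ny; ++j)
    for (int i = 0; i < m.nx; ++i) {
      int t0 = S.bz0(i, j), t1 = S.bz1(i, j);
      if (t0 != 2) S.w[m.iw(i, j, 0)] = (t0 == 1) ? S.uin : 0.0;
      if (t1 != 2) S.w[m.iw(i, j, m.nz)] = (t1 == 1) ? -S.uin : 0.0;
    }
}

double inlet_mass_flux(const State& S) {
  const Mesh& m = S.m;
  double min_ = 0.0;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j) {
      if (S.bx0(j, k) == 1) min_ += S.rho * m.Ax * S.uin;
      if (S.bx1(j, k) == 1) min_ += S.rho * m.Ax * S.uin;
    }
  for (int k = 0; k < m.nz; ++k)
    for (int i = 0; i < m.nx; ++i) {
      if (S.by0(i, k) == 1) min_ += S.rho * m.Ay * S.uin;
      if (S.by1(i, k) == 1) min_ += S.rho * m.Ay * S.uin;
    }
  for (int j = 0; j < m.ny; ++j)
    for (int i = 0; i < m.nx; ++i) {
      if (S.bz0(i, j) == 1) min_ += S.rho * m.Az * S.uin;
      if (S.bz1(i, j) == 1) min_ += S.rho * m.Az * S.uin;
    }
  return min_;
}

// Zero-gradient copy to outflow faces, clamp to outward flow, then scale so
// total outflow balances total inflow exactly.
void outlet_update(State& S) {
  const Mesh& m = S.m;
  double min_ = inlet_mass_flux(S);
  double mout = 0.0, aout = 0.0;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j) {
      if (S.bx0(j, k) == 2) {
        double q = std::min(S.u[m.iu(1, j, k)], 0.0); // outward is -x
        S.u[m.iu(0, j, k)] = q;
        mout += -S.rho * m.Ax * q; aout += m.Ax;
      }
      if (S.bx1(j, k) == 2) {
        double q = std::max(S.u[m.iu(m.nx - 1, j, k)], 0.0);
        S.u[m.iu(m.nx, j, k)] = q;
        mout += S.rho * m.Ax * q; aout += m.Ax;
      }
    }
  for (int k = 0; k < m.nz; ++k)
    for (int i = 0; i < m.nx; ++i) {
      if (S.by0(i, k) == 2) {
        double q = std::min(S.v[m.iv(i, 1, k)], 0.0);
        S.v[m.iv(i, 0, k)] = q;
        mout += -S.rho * m.Ay * q; aout += m.Ay;
      }
      if (S.by1(i, k) == 2) {
        double q = std::max(S.v[m.iv(i, m.ny - 1, k)], 0.0);
        S.v[m.iv(i, m.ny, k)] = q;
        mout += S.rho * m.Ay * q; aout += m.Ay;
      }
    }
  for (int j = 0; j < m.ny; ++j)
    for (int i = 0; i < m.nx; ++i) {
      if (S.bz0(i, j) == 2) {
        double q = std::min(S.w[m.iw(i, j, 1)], 0.0);
        S.w[m.iw(i, j, 0)] = q;
        mout += -S.rho * m.Az * q; aout += m.Az;
      }
      if (S.bz1(i, j) == 2) {
        double q = std::max(S.w[m.iw(i, j, m.nz - 1)], 0.0);
        S.w[m.iw(i, j, m.nz)] = q;
        mout += S.rho * m.Az * q; aout += m.Az;
      }
    }
  if (aout <= 0.0) return; // enclosed cavity: nothing to balance
  if (mout > 1e-14 * std::max(min_, 1e-300)) {
    double f = min_ / mout;
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j) {
        if (S.bx0(j, k) == 2) S.u[m.iu(0, j, k)] *= f;
        if (S.bx1(j, k) == 2) S.u[m.iu(m.nx, j, k)] *= f;
      }
    for (int k = 0; k < m.nz; ++k)
      for (int i = 0; i < m.nx; ++i) {
        if (S.by0(i, k) == 2) S.v[m.iv(i, 0, k)] *= f;
        if (S.by1(i, k) == 2) S.v[m.iv(i, m.ny, k)] *= f;
      }
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        if (S.bz0(i, j) == 2) S.w[m.iw(i, j, 0)] *= f;
        if (S.bz1(i, j) == 2) S.w[m.iw(i, j, m.nz)] *= f;
      }
  } else {
    double q = min_ / (S.rho * aout); // uniform outward startup profile
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j) {
        if (S.bx0(j, k) == 2) S.u[m.iu(0, j, k)] = -q;
        if (S.bx1(j, k) == 2) S.u[m.iu(m.nx, j, k)] = q;
      }
    for (int k = 0; k < m.nz; ++k)
      for (int i = 0; i < m.nx; ++i) {
        if (S.by0(i, k) == 2) S.v[m.iv(i, 0, k)] = -q;
        if (S.by1(i, k) == 2) S.v[m.iv(i, m.ny, k)] = q;
      }
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        if (S.bz0(i, j) == 2) S.w[m.iw(i, j, 0)] = -q;
        if (S.bz1(i, j) == 2) S.w[m.iw(i, j, m.nz)] = q;
      }
  }
}

// Assemble and relax one momentum component. comp: 0=u, 1=v, 2=w.
// Returns the unrelaxed absolute residual sum.
double momentum_component(State& S, int comp, int nsweep) {
  const Mesh& m = S.m;
  int n = (comp == 0) ? m.nu() : (comp == 1) ? m.nv() : m.nw();
  std::vector<double>& phi = (comp == 0) ? S.u : (comp == 1) ? S.v : S.w;
  std::vector<double>& dcoef = (comp == 0) ? S.du : (comp == 1) ? S.dv : S.dw;
  std::fill(S.aP.begin(), S.aP.begin() + n, 1.0);
  std::fill(S.aE.begin(), S.aE.begin() + n, 0.0);
  std::fill(S.aW.begin(), S.aW.begin() + n, 0.0);
  std::fill(S.aN.begin(), S.aN.begin() + n, 0.0);
  std::fill(S.aS.begin(), S.aS.begin() + n, 0.0);
  std::fill(S.aT.begin(), S.aT.begin() + n, 0.0);
  std::fill(S.aB.begin(), S.aB.begin() + n, 0.0);
  std::fill(S.bb.begin(), S.bb.begin() + n, 0.0);
  std::fill(dcoef.begin(), dcoef.end(), 0.0);

  double resid = 0.0;
  const double Ax = m.Ax, Ay = m.Ay, Az = m.Az;
  // loop bounds of the interior unknowns
  int i0 = (comp == 0) ? 1 : 0, i1 = (comp == 0) ? m.nx - 1 : m.nx - 1;
  int j0 = (comp == 1) ? 1 : 0, j1 = (comp == 1) ? m.ny - 1 : m.ny - 1;
  int k0 = (comp == 2) ? 1 : 0, k1 = (comp == 2) ? m.nz - 1 : m.nz - 1;

  for (int k = k0; k <= k1; ++k)
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        int id, cM, cP; // cells on the minus/plus side of this face
        double Anorm;
        if (comp == 0) { id = m.iu(i, j, k); cM = m.cell(i - 1, j, k); cP = m.cell(i, j, k); Anorm = Ax; }
        else if (comp == 1) { id = m.iv(i, j, k); cM = m.cell(i, j - 1, k); cP = m.cell(i, j, k); Anorm = Ay; }
        else { id = m.iw(i, j, k); cM = m.cell(i, j, k - 1); cP = m.cell(i, j, k); Anorm = Az; }

        double me_face = 0.5 * (S.mueff_cell(cM) + S.mueff_cell(cP));
        double me_M = S.mueff_cell(cM), me_P = S.mueff_cell(cP);

        // mass fluxes over the six faces of this momentum CV
        double Fe, Fw, Fn, Fs, Ft, Fb;
        if (comp == 0) {
          Fe = 0.5 * S.rho * Ax * (S.u[m.iu(i, j, k)] + S.u[m.iu(i + 1, j, k)]);
          Fw = 0.5 * S.rho * Ax * (S.u[m.iu(i - 1, j, k)] + S.u[m.iu(i, j, k)]);
          Fn = 0.5 * S.rho * Ay * (S.v[m.iv(i - 1, j + 1, k)] + S.v[m.iv(i, j + 1, k)]);
          Fs = 0.5 * S.rho * Ay * (S.v[m.iv(i - 1, j, k)] + S.v[m.iv(i, j, k)]);
          Ft = 0.5 * S.rho * Az * (S.w[m.iw(i - 1, j, k + 1)] + S.w[m.iw(i, j, k + 1)]);
          Fb = 0.5 * S.rho * Az * (S.w[m.iw(i - 1, j, k)] + S.w[m.iw(i, j, k)]);
        } else if (comp == 1) {
          Fe = 0.5 * S.rho * Ax * (S.u[m.iu(i + 1, j - 1, k)] + S.u[m.iu(i + 1, j, k)]);
          Fw = 0.5 * S.rho * Ax * (S.u[m.iu(i, j - 1, k)] + S.u[m.iu(i, j, k)]);
          Fn = 0.5 * S.rho * Ay * (S.v[m.iv(i, j, k)] + S.v[m.iv(i, j + 1, k)]);
          Fs = 0.5 * S.rho * Ay * (S.v[m.iv(i, j - 1, k)] + S.v[m.iv(i, j, k)]);
          Ft = 0.5 * S.rho * Az * (S.w[m.iw(i, j - 1, k + 1)] + S.w[m.iw(i, j, k + 1)]);
          Fb = 0.5 * S.rho * Az * (S.w[m.iw(i, j - 1, k)] + S.w[m.iw(i, j, k)]);
        } else {
          Fe = 0.5 * S.rho * Ax * (S.u[m.iu(i + 1, j, k - 1)] + S.u[m.iu(i + 1, j, k)]);
          Fw = 0.5 * S.rho * Ax * (S.u[m.iu(i, j, k - 1)] + S.u[m.iu(i, j, k)]);
          Fn = 0.5 * S.rho * Ay * (S.v[m.iv(i, j + 1, k - 1)] + S.v[m.iv(i, j + 1, k)]);
          Fs = 0.5 * S.rho * Ay * (S.v[m.iv(i, j, k - 1)] + S.v[m.iv(i, j, k)]);
          Ft = 0.5 * S.rho * Az * (S.w[m.iw(i, j, k)] + S.w[m.iw(i, j, k + 1)]);
          Fb = 0.5 * S.rho * Az * (S.w[m.iw(i, j, k - 1)] + S.w[m.iw(i, j, k)]);
        }

        double sumA = 0.0, sumF = Fe - Fw + Fn - Fs + Ft - Fb, b = 0.0;

        // helper lambdas ------------------------------------------------
        auto interior = [&](double& store, double D, double F) {
          double a = hybrid_coef(D, F, S.scheme);
          store = a; sumA += a;
        };
        // tangential boundary face: tag decides Dirichlet vs zero-gradient
        auto tangential = [&](int tag, double D, double F, double wallval) {
          if (dirichlet_tag(tag)) {
            double a = hybrid_coef(2.0 * D, F, S.scheme);
            sumA += a; b += a * wallval;
          }
          // zero-gradient: no diffusion, advection handled by sumF
        };

        // normal-direction neighbours (always stored values in the arrays)
        if (comp == 0) {
          interior(S.aE[id], me_P * Ax / m.dx, Fe);
          interior(S.aW[id], me_M * Ax / m.dx, -Fw);
        } else if (comp == 1) {
          interior(S.aN[id], me_P * Ay / m.dy, Fn);
          interior(S.aS[id], me_M * Ay / m.dy, -Fs);
        } else {
          interior(S.aT[id], me_P * Az / m.dz, Ft);
          interior(S.aB[id], me_M * Az / m.dz, -Fb);
        }

        // transverse directions
        if (comp == 0) {
          // y-direction
          if (j < m.ny - 1) interior(S.aN[id], me_face * Ay / m.dy, Fn);
          else tangential(combine_tags(S.by1(i - 1, k), S.by1(i, k)), me_face * Ay / m.dy, Fn, 0.0);
          if (j > 0) interior(S.aS[id], me_face * Ay / m.dy, -Fs);
          else tangential(combine_tags(S.by0(i - 1, k), S.by0(i, k)), me_face * Ay / m.dy, -Fs, 0.0);
          // z-direction (lid drives u)
          if (k < m.nz - 1) interior(S.aT[id], me_face * Az / m.dz, Ft);
          else {
            int tg = combine_tags(S.bz1(i - 1, j), S.bz1(i, j));
            tangential(tg, me_face * Az / m.dz, Ft, tg == 4 ? S.lid_u : 0.0);
          }
          if (k > 0) interior(S.aB[id], me_face * Az / m.dz, -Fb);
          else tangential(combine_tags(S.bz0(i - 1, j), S.bz0(i, j)), me_face * Az / m.dz, -Fb, 0.0);
        } else if (comp == 1) {
          if (i < m.nx - 1) interior(S.aE[id], me_face * Ax / m.dx, Fe);
          else tangential(combine_tags(S.bx1(j - 1, k), S.bx1(j, k)), me_face * Ax / m.dx, Fe, 0.0);
          if (i > 0) interior(S.aW[id], me_face * Ax / m.dx, -Fw);
          else tangential(combine_tags(S.bx0(j - 1, k), S.bx0(j, k)), me_face * Ax / m.dx, -Fw, 0.0);
          if (k < m.nz - 1) interior(S.aT[id], me_face * Az / m.dz, Ft);
          else tangential(combine_tags(S.bz1(i, j - 1), S.bz1(i, j)), me_face * Az / m.dz, Ft, 0.0);
          if (k > 0) interior(S.aB[id], me_face * Az / m.dz, -Fb);
          else tangential(combine_tags(S.bz0(i, j - 1), S.bz0(i, j)), me_face * Az / m.dz, -Fb, 0.0);
        } else {
          if (i < m.nx - 1) interior(S.aE[id], me_face * Ax / m.dx, Fe);
          else tangential(combine_tags(S.bx1(j, k - 1), S.bx1(j, k)), me_face * Ax / m.dx, Fe, 0.0);
          if (i > 0) interior(S.aW[id], me_face * Ax / m.dx, -Fw);
          else tangential(combine_tags(S.bx0(j, k - 1), S.bx0(j, k)), me_face * Ax / m.dx, -Fw, 0.0);
          if (j < m.ny - 1) interior(S.aN[id], me_face * Ay / m.dy, Fn);
          else tangential(combine_tags(S.by1(i, k - 1), S.by1(i, k)), me_face * Ay / m.dy, Fn, 0.0);
          if (j > 0) interior(S.aS[id], me_face * Ay / m.dy, -Fs);
          else tangential(combine_tags(S.by0(i, k - 1), S.by0(i, k)), me_face * Ay / m.dy, -Fs, 0.0);
        }

        double ap = sumA + sumF;
        if (ap <= 0.0) ap = sumA + std::abs(sumF) + 1e-300;
        b += (S.p[cM] - S.p[cP]) * Anorm;

        // unrelaxed residual with current values
        double sum_nb = 0.0;
        if (comp == 0) {
          sum_nb += S.aE[id] * S.u[m.iu(i + 1, j, k)] + S.aW[id] * S.u[m.iu(i - 1, j, k)];
          if (j < m.ny - 1) sum_nb += S.aN[id] * S.u[m.iu(i, j + 1, k)];
          if (j > 0) sum_nb += S.aS[id] * S.u[m.iu(i, j - 1, k)];
          if (k < m.nz - 1) sum_nb += S.aT[id] * S.u[m.iu(i, j, k + 1)];
          if (k > 0) sum_nb += S.aB[id] * S.u[m.iu(i, j, k - 1)];
          resid += std::abs(ap * S.u[id] - sum_nb - b);
        } else if (comp == 1) {
          sum_nb += S.aN[id] * S.v[m.iv(i, j + 1, k)] + S.aS[id] * S.v[m.iv(i, j - 1, k)];
          if (i < m.nx - 1) sum_nb += S.aE[id] * S.v[m.iv(i + 1, j, k)];
          if (i > 0) sum_nb += S.aW[id] * S.v[m.iv(i - 1, j, k)];
          if (k < m.nz - 1) sum_nb += S.aT[id] * S.v[m.iv(i, j, k + 1)];
          if (k > 0) sum_nb += S.aB[id] * S.v[m.iv(i, j, k - 1)];
          resid += std::abs(ap * S.v[id] - sum_nb - b);
        } else {
          sum_nb += S.aT[id] * S.w[m.iw(i, j, k + 1)] + S.aB[id] * S.w[m.iw(i, j, k - 1)];
          if (i < m.nx - 1) sum_nb += S.aE[id] * S.w[m.iw(i + 1, j, k)];
          if (i > 0) sum_nb += S.aW[id] * S.w[m.iw(i - 1, j, k)];
          if (j < m.ny - 1) sum_nb += S.aN[id] * S.w[m.iw(i, j + 1, k)];
          if (j > 0) sum_nb += S.aS[id] * S.w[m.iw(i, j - 1, k)];
          resid += std::abs(ap * S.w[id] - sum_nb - b);
        }

        // under-relaxation
        double apr = ap / S.alpha_u;
        S.aP[id] = apr;
        S.bb[id] = b + (1.0 - S.alpha_u) * apr * phi[id];
        dcoef[id] = Anorm / apr;
      }

  // Gauss-Seidel sweeps (alternating direction)
  for (int s = 0; s < nsweep; ++s) {
    bool fwd = (s % 2 == 0);
    for (int kk_ = 0; kk_ < (k1 - k0 + 1); ++kk_)
      for (int jj_ = 0; jj_ < (j1 - j0 + 1); ++jj_)
        for (int ii_ = 0; ii_ < (i1 - i0 + 1); ++ii_) {
          int k = fwd ? k0 + kk_ : k1 - kk_;
          int j = fwd ? j0 + jj_ : j1 - jj_;
          int i = fwd ? i0 + ii_ : i1 - ii_;
          int id;
          double s_nb = 0.0;
          if (comp == 0) {
            id = m.iu(i, j, k);
            s_nb = S.aE[id] * S.u[m.iu(i + 1, j, k)] + S.aW[id] * S.u[m.iu(i - 1, j, k)];
            if (j < m.ny - 1) s_nb += S.aN[id] * S.u[m.iu(i, j + 1, k)];
            if (j > 0) s_nb += S.aS[id] * S.u[m.iu(i, j - 1, k)];
            if (k < m.nz - 1) s_nb += S.aT[id] * S.u[m.iu(i, j, k + 1)];
            if (k > 0) s_nb += S.aB[id] * S.u[m.iu(i, j, k - 1)];
            S.u[id] = (s_nb + S.bb[id]) / S.aP[id];
          } else if (comp == 1) {
            id = m.iv(i, j, k);
            s_nb = S.aN[id] * S.v[m.iv(i, j + 1, k)] + S.aS[id] * S.v[m.iv(i, j - 1, k)];
            if (i < m.nx - 1) s_nb += S.aE[id] * S.v[m.iv(i + 1, j, k)];
            if (i > 0) s_nb += S.aW[id] * S.v[m.iv(i - 1, j, k)];
            if (k < m.nz - 1) s_nb += S.aT[id] * S.v[m.iv(i, j, k + 1)];
            if (k > 0) s_nb += S.aB[id] * S.v[m.iv(i, j, k - 1)];
            S.v[id] = (s_nb + S.bb[id]) / S.aP[id];
          } else {
            id = m.iw(i, j, k);
            s_nb = S.aT[id] * S.w[m.iw(i, j, k + 1)] + S.aB[id] * S.w[m.iw(i, j, k - 1)];
            if (i < m.nx - 1) s_nb += S.aE[id] * S.w[m.iw(i + 1, j, k)];
            if (i > 0) s_nb += S.aW[id] * S.w[m.iw(i - 1, j, k)];
            if (j < m.ny - 1) s_nb += S.aN[id] * S.w[m.iw(i, j + 1, k)];
            if (j > 0) s_nb += S.aS[id] * S.w[m.iw(i, j - 1, k)];
            S.w[id] = (s_nb + S.bb[id]) / S.aP[id];
          }
        }
  }
  return resid;
}

double cell_divergence(const State& S, int i, int j, int k) {
  const Mesh& m = S.m;
  return S.rho * (m.Ax * (S.u[m.iu(i + 1, j, k)] - S.u[m.iu(i, j, k)])
                + m.Ay * (S.v[m.iv(i, j + 1, k)] - S.v[m.iv(i, j, k)])
                + m.Az * (S.w[m.iw(i, j, k + 1)] - S.w[m.iw(i, j, k)]));
}

// SIMPLE pressure-correction step. Returns the scaled continuity residual
// numerator (sum |mass imbalance|).
double pressure_correction(State& S, std::vector<double>& pc, int max_sweep) {
  const Mesh& m = S.m;
  int n = m.ncell();
  std::fill(pc.begin(), pc.end(), 0.0);
  std::vector<double>& ap = S.aP; std::vector<double>& rhs = S.bb;
  double rc = 0.0;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        int c = m.cell(i, j, k);
        double a = 0.0;
        if (i < m.nx - 1) a += S.rho * m.Ax * S.du[m.iu(i + 1, j, k)];
        if (i > 0) a += S.rho * m.Ax * S.du[m.iu(i, j, k)];
        if (j < m.ny - 1) a += S.rho * m.Ay * S.dv[m.iv(i, j + 1, k)];
        if (j > 0) a += S.rho * m.Ay * S.dv[m.iv(i, j, k)];
        if (k < m.nz - 1) a += S.rho * m.Az * S.dw[m.iw(i, j, k + 1)];
        if (k > 0) a += S.rho * m.Az * S.dw[m.iw(i, j, k)];
        ap[c] = (a > 0.0) ? a : 1.0;
        double div = cell_divergence(S, i, j, k);
        rhs[c] = -div;
        rc += std::abs(div);
      }
  // SOR on the correction equation; all-Neumann (fluxes fixed on
  // boundaries), reference fixed afterwards by subtracting pc[0].
  const double omega = 1.5;
  for (int s = 0; s < max_sweep; ++s) {
    double change = 0.0, norm = 0.0;
    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i < m.nx; ++i) {
          int c = m.cell(i, j, k);
          double s_nb = 0.0;
          if (i < m.nx - 1) s_nb += S.rho * m.Ax * S.du[m.iu(i + 1, j, k)] * pc[m.cell(i + 1, j, k)];
          if (i > 0) s_nb += S.rho * m.Ax * S.du[m.iu(i, j, k)] * pc[m.cell(i - 1, j, k)];
          if (j < m.ny - 1) s_nb += S.rho * m.Ay * S.dv[m.iv(i, j + 1, k)] * pc[m.cell(i, j + 1, k)];
          if (j > 0) s_nb += S.rho * m.Ay * S.dv[m.iv(i, j, k)] * pc[m.cell(i, j - 1, k)];
          if (k < m.nz - 1) s_nb += S.rho * m.Az * S.dw[m.iw(i, j, k + 1)] * pc[m.cell(i, j, k + 1)];
          if (k > 0) s_nb += S.rho * m.Az * S.dw[m.iw(i, j, k)] * pc[m.cell(i, j, k - 1)];
          double pnew = (s_nb + rhs[c]) / ap[c];
          double upd = pc[c] + omega * (pnew - pc[c]);
          change += std::abs(upd - pc[c]);
          norm += std::abs(upd);
          pc[c] = upd;
        }
    if (change < 1e-3 * (norm + 1e-300)) break;
  }
  double pref = pc[0];
  for (int c = 0; c < n; ++c) pc[c] -= pref;

  // velocity and pressure corrections (interior faces only)
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 1; i < m.nx; ++i) {
        int id = m.iu(i, j, k);
        S.u[id] += S.du[id] * (pc[m.cell(i - 1, j, k)] - pc[m.cell(i, j, k)]);
      }
  for (int k = 0; k < m.nz; ++k)
    for (int j = 1; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        int id = m.iv(i, j, k);
        S.v[id] += S.dv[id] * (pc[m.cell(i, j - 1, k)] - pc[m.cell(i, j, k)]);
      }
  for (int k = 1; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        int id = m.iw(i, j, k);
        S.w[id] += S.dw[id] * (pc[m.cell(i, j, k - 1)] - pc[m.cell(i, j, k)]);
      }
  for (int c = 0; c < n; ++c) S.p[c] += S.alpha_p * pc[c];
  return rc;
}

// --- standard k-epsilon transport update -----------------------------------

void cell_center_velocity(const State& S, std::vector<double>& uc,
                          std::vector<double>& vc, std::vector<double>& wc) {
  const Mesh& m = S.m;
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        int c = m.cell(i, j, k);
        uc[c] = 0.5 * (S.u[m.iu(i, j, k)] + S.u[m.iu(i + 1, j, k)]);
        vc[c] = 0.5 * (S.v[m.iv(i, j, k)] + S.v[m.iv(i, j + 1, k)]);
        wc[c] = 0.5 * (S.w[m.iw(i, j, k)] + S.w[m.iw(i, j, k + 1)]);
      }
}

// central differences with edge replication
inline double grad1(const std::vector<double>& f, int cm, int c, int cp,
                    bool has_m, bool has_p, double d) {
  if (has_m && has_p) return (f[cp] - f[cm]) / (2.0 * d);
  if (has_p) return (f[cp] - f[c]) / d;
  if (has_m) return (f[c] - f[cm]) / d;
  return 0.0;
}

// One under-relaxed update of k, epsilon and mut on the frozen velocity
// field. Wall-adjacent cells use equilibrium log-law wall functions.
void keps_update(State& S, int nsweep) {
  const Mesh& m = S.m;
  int n = m.ncell();
  std::vector<double> uc(n), vc(n), wc(n), prod(n), ypw(n, -1.0), utan(n, 0.0);
  cell_center_velocity(S, uc, vc, wc);

  // strain-rate production
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        int c = m.cell(i, j, k);
        bool im = i > 0, ip = i < m.nx - 1, jm = j > 0, jp = j < m.ny - 1,
             km = k > 0, kp = k < m.nz - 1;
        int cim = im ? m.cell(i - 1, j, k) : c, cip = ip ? m.cell(i + 1, j, k) : c;
        int cjm = jm ? m.cell(i, j - 1, k) : c, cjp = jp ? m.cell(i, j + 1, k) : c;
        int ckm = km ? m.cell(i, j, k - 1) : c, ckp = kp ? m.cell(i, j, k + 1) : c;
        double ux = (S.u[m.iu(i + 1, j, k)] - S.u[m.iu(i, j, k)]) / m.dx;
        double vy = (S.v[m.iv(i, j + 1, k)] - S.v[m.iv(i, j, k)]) / m.dy;
        double wz = (S.w[m.iw(i, j, k + 1)] - S.w[m.iw(i, j, k)]) / m.dz;
        double uy = grad1(uc, cjm, c, cjp, jm, jp, m.dy);
        double uz = grad1(uc, ckm, c, ckp, km, kp, m.dz);
        double vx = grad1(vc, cim, c, cip, im, ip, m.dx);
        double vz = grad1(vc, ckm, c, ckp, km, kp, m.dz);
        double wx = grad1(wc, cim, c, cip, im, ip, m.dx);
        double wy = grad1(wc, cjm, c, cjp, jm, jp, m.dy);
        double s2 = 2.0 * (ux * ux + vy * vy + wz * wz)
                  + (uy + vx) * (uy + vx) + (uz + wx) * (uz + wx)
                  + (vz + wy) * (vz + wy);
        prod[c] = S.mut[c] * s2;
      }

  // wall-adjacent handling: nearest wall distance and tangential speed
  for (int k = 0; k < m.nz; ++k)
    for (int j = 0; j < m.ny; ++j)
      for (int i = 0; i < m.nx; ++i) {
        int c = m.cell(i, j, k);
        double yp = -1.0, ut = 0.0;
        auto wall = [&](bool cond, int tag, double dist, double t1, double t2) {
          if (cond && (tag == 0 || tag == 4)) {
            if (yp < 0.0 || dist < yp) {
              yp = dist;
              ut = std::sqrt(t1 * t1 + t2 * t2);
            }
          }
        };
        wall(i == 0, S.bx0(j, k), 0.5 * m.dx, vc[c], wc[c]);
        wall(i == m.nx - 1, S.bx1(j, k), 0.5 * m.dx, vc[c], wc[c]);
        wall(j == 0, S.by0(i, k), 0.5 * m.dy, uc[c], wc[c]);
        wall(j == m.ny - 1, S.by1(i, k), 0.5 * m.dy, uc[c], wc[c]);
        wall(k == 0, S.bz0(i, j), 0.5 * m.dz, uc[c], vc[c]);
        wall(k == m.nz - 1, S.bz1(i, j), 0.5 * m.dz, uc[c], vc[c]);
        ypw[c] = yp; utan[c] = ut;
        if (yp > 0.0) {
          // replace production by the wall-shear form
          double sqrtk = std::sqrt(std::max(S.tk[c], 1e-14));
          double ustar = std::pow(CMU, 0.25) * sqrtk;
          double yplus = S.rho * ustar * yp / S.mu;
          double tauw;
          if (yplus < 11.63) tauw = S.mu * ut / yp;
          else tauw = S.rho * KAPPA * ustar * ut / std::log(EWALL * yplus);
          prod[c] = tauw * ut / yp;
        }
      }

  // transport solve for k then epsilon
  for (int eq = 0; eq < 2; ++eq) {
    std::vector<double>& phi = (eq == 0) ? S.tk : S.te;
    double sig = (eq == 0) ? SIGK : SIGE;
    double bval_in = (eq == 0) ? S.kin : S.epsin;
    int nloc = n;
    std::fill(S.aP.begin(), S.aP.begin() + nloc, 1.0);
    std::fill(S.aE.begin(), S.aE.begin() + nloc, 0.0);
    std::fill(S.aW.begin(), S.aW.begin() + nloc, 0.0);
    std::fill(S.aN.begin(), S.aN.begin() + nloc, 0.0);
    std::fill(S.aS.begin(), S.aS.begin() + nloc, 0.0);
    std::fill(S.aT.begin(), S.aT.begin() + nloc, 0.0);
    std::fill(S.aB.begin(), S.aB.begin() + nloc, 0.0);
    std::fill(S.bb.begin(), S.bb.begin() + nloc, 0.0);

    for (int k = 0; k < m.nz; ++k)
      for (int j = 0; j < m.ny; ++j)
        for (int i = 0; i < m.nx; ++i) {
          int c = m.cell(i, j, k);
          double sumA = 0.0, sumF = 0.0, b = 0.0;
          auto face = [&](double& store, bool interior_face, int tag, double F,
                          double gam, double area, double d) {
            double D = gam * area / d;
            sumF += F;
            if (interior_face) {
              double a = hybrid_coef(D, F, S.scheme);
              store = a; sumA += a;
            } else if (tag == 1) { // inlet: Dirichlet at half cell
              double a = hybrid_coef(2.0 * D, F, S.scheme);
              sumA += a; b += a * bval_in;
            }
            // walls, slip and outflow: zero diffusive flux; advection via sumF
          };
          double gm;
          gm = S.mu + 0.5 * (S.mut[c] + (i < m.nx - 1 ? S.mut[m.cell(i + 1, j, k)] : S.mut[c])) / sig;
          face(S.aE[c], i < m.nx - 1, (i == m.nx - 1) ? S.bx1(j, k) : -1,
               S.rho * m.Ax * S.u[m.iu(i + 1, j, k)], gm, m.Ax, m.dx);
          gm = S.mu + 0.5 * (S.mut[c] + (i > 0 ? S.mut[m.cell(i - 1, j, k)] : S.mut[c])) / sig;
          face(S.aW[c], i > 0, (i == 0) ? S.bx0(j, k) : -1,
               -S.rho * m.Ax * S.u[m.iu(i, j, k)], gm, m.Ax, m.dx);
          gm = S.mu + 0.5 * (S.mut[c] + (j < m.ny - 1 ? S.mut[m.cell(i, j + 1, k)] : S.mut[c])) / sig;
          face(S.aN[c], j < m.ny - 1, (j == m.ny - 1) ? S.by1(i, k) : -1,
               S.rho * m.Ay * S.v[m.iv(i, j + 1, k)], gm, m.Ay, m.dy);
          gm = S.mu + 0.5 * (S.mut[c] + (j > 0 ? S.mut[m.cell(i, j - 1, k)] : S.mut[c])) / sig;
          face(S.aS[c], j > 0, (j == 0) ? S.by0(i, k) : -1,
               -S.rho * m.Ay * S.v[m.iv(i, j, k)], gm, m.Ay, m.dy);
          gm = S.mu + 0.5 * (S.mut[c] + (k < m.nz - 1 ? S.mut[m.cell(i, j, k + 1)] : S.mut[c])) / sig;
          face(S.aT[c], k < m.nz - 1, (k == m.nz - 1) ? S.bz1(i, j) : -1,
               S.rho * m.Az * S.w[m.iw(i, j, k + 1)], gm, m.Az, m.dz);
          gm = S.mu + 0.5 * (S.mut[c] + (k > 0 ? S.mut[m.cell(i, j, k - 1)] : S.mut[c])) / sig;
          face(S.aB[c], k > 0, (k == 0) ? S.bz0(i, j) : -1,
               -S.rho * m.Az * S.w[m.iw(i, j, k)], gm, m.Az, m.dz);

          double kc = std::max(S.tk[c], 1e-14);
          double ec = std::max(S.te[c], 1e-20);
          double ap = sumA + sumF;
          if (eq == 0) {
            b += prod[c] * m.vol;
            ap += S.rho * (ec / kc) * m.vol; // dissipation, implicit
          } else {
            b += C1E * (ec / kc) * prod[c] * m.vol;
            ap += C2E * S.rho * (ec / kc) * m.vol;
          }
          if (ap <= 0.0) ap = sumA + std::abs(sumF) + 1e-300;
          double apr = ap / S.alpha_t;
          S.aP[c] = apr;
          S.bb[c] = b + (1.0 - S.alpha_t) * apr * phi[c];
          if (eq == 1 && ypw[c] > 0.0) {
            // fix epsilon from local equilibrium in wall cells
            double ew = std::pow(CMU, 0.75) * std::pow(kc, 1.5) / (KAPPA * ypw[c]);
            S.aP[c] = 1.0; S.bb[c] = ew;
            S.aE[c] = S.aW[c] = S.aN[c] = S.aS[c] = S.aT[c] = S.aB[c] = 0.0;
          }
        }

    for (int s = 0; s < nsweep; ++s)
      for (int k = 0; k < m.nz; ++k)
        for (int j = 0; j < m.ny; ++j)
          for (int i = 0; i < m.nx; ++i) {
            int c = m.cell(i, j, k);
            double s_nb = 0.0;
            if (i < m.nx - 1) s_nb += S.aE[c] * phi[m.cell(i + 1, j, k)];
            if (i > 0) s_nb += S.aW[c] * phi[m.cell(i - 1, j, k)];
            if (j < m.ny - 1) s_nb += S.aN[c] * phi[m.cell(i, j + 1, k)];
            if (j > 0) s_nb += S.aS[c] * phi[m.cell(i, j - 1, k)];
            if (k < m.nz - 1) s_nb += S.aT[c] * phi[m.cell(i, j, k + 1)];
            if (k > 0) s_nb += S.aB[c] * phi[m.cell(i, j, k - 1)];
            phi[c] = (s_nb + S.bb[c]) / S.aP[c];
          }
    for (int c = 0; c < n; ++c)
      phi[c] = std::max(phi[c], (eq == 0) ? 1e-14 : 1e-20);
  }

  for (int c = 0; c < n; ++c) {
    double mt = S.rho * CMU * S.tk[c] * S.tk[c] / S.te[c];
    mt = std::min(mt, 1e5 * S.mu);
    S.mut[c] = S.alpha_t * mt + (1.0 - S.alpha_t) * S.mut[c];
  }
}

State make_state(int nx, int ny, int nz, double dx, double dy, double dz,
                 IntegerMatrix bx0, IntegerMatrix bx1, IntegerMatrix by0,
                 IntegerMatrix by1, IntegerMatrix bz0, IntegerMatrix bz1,
                 double uin, double lid_u, double rho, double mu,
                 double nu_eff, int closure, int scheme,
                 double alpha_u, double alpha_p, double alpha_t,
                 double kin, double epsin) {
  State S;
  S.m = Mesh{nx, ny, nz, dx, dy, dz, dy * dz, dx * dz, dx * dy, dx * dy * dz};
  S.bx0 = bx0; S.bx1 = bx1; S.by0 = by0; S.by1 = by1; S.bz0 = bz0; S.bz1 = bz1;
  S.uin = uin; S.lid_u = lid_u; S.rho = rho; S.mu = mu; S.nu_eff = nu_eff;
  S.closure = closure; S.scheme = scheme;
  S.alpha_u = alpha_u; S.alpha_p = alpha_p; S.alpha_t = alpha_t;
  S.kin = kin; S.epsin = epsin;
  S.u.assign(S.m.nu(), 0.0); S.v.assign(S.m.nv(), 0.0); S.w.assign(S.m.nw(), 0.0);
  S.p.assign(S.m.ncell(), 0.0);
  S.tk.assign(S.m.ncell(), std::max(kin, 1e-14));
  S.te.assign(S.m.ncell(), std::max(epsin, 1e-20));
  S.mut.assign(S.m.ncell(), 0.0);
  if (closure == 1)
    for (int c = 0; c < S.m.ncell(); ++c)
      S.mut[c] = std::min(rho * CMU * S.tk[c] * S.tk[c] / S.te[c], 1e5 * mu);
  S.du.assign(S.m.nu(), 0.0); S.dv.assign(S.m.nv(), 0.0); S.dw.assign(S.m.nw(), 0.0);
  int nmax = std::max(std::max(S.m.nu(), S.m.nv()), std::max(S.m.nw(), S.m.ncell()));
  S.aE.assign(nmax, 0.0); S.aW.assign(nmax, 0.0); S.aN.assign(nmax, 0.0);
  S.aS.assign(nmax, 0.0); S.aT.assign(nmax, 0.0); S.aB.assign(nmax, 0.0);
  S.aP.assign(nmax, 1.0); S.bb.assign(nmax, 0.0);
  return S;
}

} // namespace

// [[Rcpp::export]]
List simple_solve_cpp(int nx, int ny, int nz, double dx, double dy, double dz,
                      IntegerMatrix bx0, IntegerMatrix bx1, IntegerMatrix by0,
                      IntegerMatrix by1, IntegerMatrix bz0, IntegerMatrix bz1,
                      double uin, double lid_u, double rho, double mu,
                      double nu_eff, int closure, int scheme, double tol,
                      int max_iter, double alpha_u, double alpha_p,
                      double alpha_t, double kin, double epsin,
                      bool verbose) {
  State S = make_state(nx, ny, nz, dx, dy, dz, bx0, bx1, by0, by1, bz0, bz1,
                       uin, lid_u, rho, mu, nu_eff, closure, scheme,
                       alpha_u, alpha_p, alpha_t, kin, epsin);
  std::vector<double> pc(S.m.ncell(), 0.0);
  std::vector<double> uold(S.m.nu()), vold(S.m.nv()), wold(S.m.nw());
  std::vector<double> hist_u, hist_v, hist_w, hist_c, hist_d;
  double ref_u = -1.0, ref_v = -1.0, ref_w = -1.0, ref_c = -1.0;
  bool converged = false;
  int iter = 0;

  set_boundary_normals(S);
  for (iter = 1; iter <= max_iter; ++iter) {
    uold = S.u; vold = S.v; wold = S.w;
    outlet_update(S);
    double ru = momentum_component(S, 0, 2);
    double rv = momentum_component(S, 1, 2);
    double rw = momentum_component(S, 2, 2);
    outlet_update(S);
    double rc = pressure_correction(S, pc, 120);
    if (S.closure == 1 && iter > 5) keps_update(S, 2);

    if (iter <= 5) {
      ref_u = std::max(ref_u, ru); ref_v = std::max(ref_v, rv);
      ref_w = std::max(ref_w, rw); ref_c = std::max(ref_c, rc);
    }
    double su = (ref_u > 1e-300) ? ru / ref_u : 0.0;
    double sv = (ref_v > 1e-300) ? rv / ref_v : 0.0;
    double sw = (ref_w > 1e-300) ? rw / ref_w : 0.0;
    double sc = (ref_c > 1e-300) ? rc / ref_c : 0.0;
    // iteration-to-iteration relative change of the velocity field
    double dnum = 0.0, dden = 0.0;
    for (size_t q = 0; q < S.u.size(); ++q) {
      dnum += std::abs(S.u[q] - uold[q]); dden += std::abs(S.u[q]);
    }
    for (size_t q = 0; q < S.v.size(); ++q) {
      dnum += std::abs(S.v[q] - vold[q]); dden += std::abs(S.v[q]);
    }
    for (size_t q = 0; q < S.w.size(); ++q) {
      dnum += std::abs(S.w[q] - wold[q]); dden += std::abs(S.w[q]);
    }
    double delta = (dden > 1e-300) ? dnum / dden : 0.0;
    hist_u.push_back(su); hist_v.push_back(sv); hist_w.push_back(sw);
    hist_c.push_back(sc); hist_d.push_back(delta);
    if (verbose && iter % 100 == 0)
      Rcpp::Rcout << "iter " << iter << " u " << su << " v " << sv
                  << " w " << sw << " cont " << sc << " delta " << delta
                  << "\n";
    if (iter > 5 && delta < tol) {
      converged = true;
      break;
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }
  // final exact global mass balance on the outflow faces
  outlet_update(S);

  int nh = hist_u.size();
  NumericMatrix hist(nh, 5);
  for (int r = 0; r < nh; ++r) {
    hist(r, 0) = hist_u[r]; hist(r, 1) = hist_v[r];
    hist(r, 2) = hist_w[r]; hist(r, 3) = hist_c[r];
    hist(r, 4) = hist_d[r];
  }
  colnames(hist) = CharacterVector::create("u", "v", "w", "continuity",
                                           "delta");

  return List::create(
    _["u"] = NumericVector(S.u.begin(), S.u.end()),
    _["v"] = NumericVector(S.v.begin(), S.v.end()),
    _["w"] = NumericVector(S.w.begin(), S.w.end()),
    _["p"] = NumericVector(S.p.begin(), S.p.end()),
    _["k"] = NumericVector(S.tk.begin(), S.tk.end()),
    _["epsilon"] = NumericVector(S.te.begin(), S.te.end()),
    _["mut"] = NumericVector(S.mut.begin(), S.mut.end()),
    _["residuals"] = hist,
    _["iterations"] = std::min(iter, max_iter),
    _["converged"] = converged);
}

// One k-epsilon update on frozen velocity fields (testing / stepping API).
// [[Rcpp::export]]
List keps_step_cpp(int nx, int ny, int nz, double dx, double dy, double dz,
                   IntegerMatrix bx0, IntegerMatrix bx1, IntegerMatrix by0,
                   IntegerMatrix by1, IntegerMatrix bz0, IntegerMatrix bz1,
                   NumericVector u, NumericVector v, NumericVector w,
                   NumericVector k0, NumericVector eps0, NumericVector mut0,
                   double rho, double mu, double alpha_t, double kin,
                   double epsin, int scheme, int nsweep) {
  State S = make_state(nx, ny, nz, dx, dy, dz, bx0, bx1, by0, by1, bz0, bz1,
                       0.0, 0.0, rho, mu, 0.0, 1, scheme, 0.7, 0.3, alpha_t,
                       kin, epsin);
  std::copy(u.begin(), u.end(), S.u.begin());
  std::copy(v.begin(), v.end(), S.v.begin());
  std::copy(w.begin(), w.end(), S.w.begin());
  std::copy(k0.begin(), k0.end(), S.tk.begin());
  std::copy(eps0.begin(), eps0.end(), S.te.begin());
  std::copy(mut0.begin(), mut0.end(), S.mut.begin());
  keps_update(S, nsweep);
  return List::create(
    _["k"] = NumericVector(S.tk.begin(), S.tk.end()),
    _["epsilon"] = NumericVector(S.te.begin(), S.te.end()),
    _["mut"] = NumericVector(S.mut.begin(), S.mut.end()));
}
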