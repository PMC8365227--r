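// 2D incompressible Navier-Stokes on a staggered (MAC) grid.
//
// Chorin projection with first-order upwind advection and explicit
// diffusion; the stent is a resistive screen on the neck v-faces whose drag
// is treated implicitly and folded into the pressure projection as a face
// mobility, so the screen stays resistive against pressure-driven flux and
// the corrected field is discretely divergence-free.
//
// Cell mask codes (shared with R): 0 solid, 1 fluid_parent, 2 fluid_sac,
// 3 neck_interface (parent-side fluid).

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

enum UType { U_WALL = 0, U_INLET = 1, U_INT = 2, U_OUT = 3 };
enum VType { V_WALL = 0, V_INT = 2 };

struct Solver {
  int nx, ny, ny_parent;
  double h, rho, mu, nu;
  std::vector<int> mask;            // nx*ny
  std::vector<int> utype;           // (nx+1)*ny
  std::vector<int> vtype;           // nx*(ny+1)
  std::vector<char> u_reflect;      // wall u-face fully inside solid?
  std::vector<char> v_reflect;
  std::vector<double> u, v, p, p_prev;
  bool have_prev = false;
  // screen: normal drag on chord v-faces, tangential drag on the u-faces of
  // the two cell rows adjacent to the chord (thin porous layer)
  std::vector<int> screen_face;     // index into v array
  std::vector<double> scr_avisc, scr_ainert;  // drag coefficients
  std::vector<int> screen_uface;    // index into u array
  std::vector<double> scr_u_avisc, scr_u_ainert;
  std::vector<double> beta_v;       // per-v-face mobility for projection
  // inlet
  std::vector<double> inlet_steady;             // ny
  std::vector<double> inlet_re, inlet_im;       // ny*K
  int K;
  double omega;

  int idu(int i, int j) const { return i + j * (nx + 1); }
  int idv(int i, int j) const { return i + j * nx; }
  int idc(int i, int j) const { return i + j * nx; }
  bool fluid(int i, int j) const { return mask[idc(i, j)] > 0; }

  // tangential-neighbor value with no-slip ghosts
  double uval(int i, int j, double uc) const {
    if (j < 0 || j >= ny) return -uc;           // domain wall: reflect
    int t = utype[idu(i, j)];
    if (t == U_WALL) return u_reflect[idu(i, j)] ? -uc : 0.0;
    return u[idu(i, j)];
  }
  double vval(int i, int j, double vc) const {
    if (i < 0) return -vc;                      // inlet plane: v = 0
    if (i >= nx) return v[idv(nx - 1, j)];      // outlet: zero gradient
    int t = vtype[idv(i, j)];
    if (t == V_WALL) return v_reflect[idv(i, j)] ? -vc : 0.0;
    return v[idv(i, j)];
  }

  double inlet_profile(int j, double t) const {
    double val = inlet_steady[j];
    for (int k = 0; k < K; ++k) {
      double ph = (k + 1) * omega * t;
      val += inlet_re[j + k * ny] * std::cos(ph) -
             inlet_im[j + k * ny] * std::sin(ph);
    }
    return val;
  }

  void classify() {
    utype.assign((nx + 1) * ny, U_WALL);
    u_reflect.assign((nx + 1) * ny, 0);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i <= nx; ++i) {
        int t = U_WALL;
        if (i == 0) t = fluid(0, j) ? U_INLET : U_WALL;
        else if (i == nx) t = fluid(nx - 1, j) ? U_OUT : U_WALL;
        else if (fluid(i - 1, j) && fluid(i, j)) t = U_INT;
        utype[idu(i, j)] = t;
        if (t == U_WALL) {
          bool lsolid = (i == 0) ? true : !fluid(i - 1, j);
          bool rsolid = (i == nx) ? true : !fluid(i, j);
          u_reflect[idu(i, j)] = (lsolid && rsolid) ? 1 : 0;
        }
      }
    }
    vtype.assign(nx * (ny + 1), V_WALL);
    v_reflect.assign(nx * (ny + 1), 0);
    for (int j = 0; j <= ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int t = V_WALL;
        if (j > 0 && j < ny && fluid(i, j - 1) && fluid(i, j)) t = V_INT;
        vtype[idv(i, j)] = t;
        if (t == V_WALL) {
          bool bsolid = (j == 0) ? true : !fluid(i, j - 1);
          bool tsolid = (j == ny) ? true : !fluid(i, j);
          v_reflect[idv(i, j)] = (bsolid && tsolid) ? 1 : 0;
        }
      }
    }
  }

  double max_speed() const {
    double m = 0;
    for (double x : u) m = std::max(m, std::fabs(x));
    for (double x : v) m = std::max(m, std::fabs(x));
    return m;
  }

  // ---- momentum predictor -------------------------------------------------
  void momentum(std::vector<double>& us, std::vector<double>& vs,
                double dt) const {
    us = u; vs = v;
    // u faces
    for (int j = 0; j < ny; ++j) {
      for (int i = 1; i < nx; ++i) {
        if (utype[idu(i, j)] != U_INT) continue;
        double uc = u[idu(i, j)];
        double uW = u[idu(i - 1, j)], uE = u[idu(i + 1, j)];
        double uS = uval(i, j - 1, uc), uN = uval(i, j + 1, uc);
        double vb = 0.25 * (vval(i - 1, j, 0) + vval(i, j, 0) +
                            vval(i - 1, j + 1, 0) + vval(i, j + 1, 0));
        double dudx = (uc > 0) ? (uc - uW) / h : (uE - uc) / h;
        double dudy = (vb > 0) ? (uc - uS) / h : (uN - uc) / h;
        double lap = (uE - 2 * uc + uW + uN - 2 * uc + uS) / (h * h);
        us[idu(i, j)] = uc + dt * (-(uc * dudx + vb * dudy) + nu * lap);
      }
    }
    // v faces
    for (int j = 1; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (vtype[idv(i, j)] != V_INT) continue;
        double vc = v[idv(i, j)];
        double vS = v[idv(i, j - 1)], vN = v[idv(i, j + 1)];
        double vW = vval(i - 1, j, vc), vE = vval(i + 1, j, vc);
        double ub = 0.25 * (u[idu(i, j - 1)] + u[idu(i + 1, j - 1)] +
                            u[idu(i, j)] + u[idu(i + 1, j)]);
        double dvdx = (ub > 0) ? (vc - vW) / h : (vE - vc) / h;
        double dvdy = (vc > 0) ? (vc - vS) / h : (vN - vc) / h;
        double lap = (vE - 2 * vc + vW + vN - 2 * vc + vS) / (h * h);
        vs[idv(i, j)] = vc + dt * (-(ub * dvdx + vc * dvdy) + nu * lap);
      }
    }
  }

  // ---- screen drag (implicit) --------------------------------------------
  void apply_screen(std::vector<double>& us, std::vector<double>& vs,
                    double dt) {
    std::fill(beta_v.begin(), beta_v.end(), 1.0);
    for (size_t k = 0; k < screen_face.size(); ++k) {
      int f = screen_face[k];
      double theta = dt * (scr_avisc[k] + scr_ainert[k] * std::fabs(vs[f])) /
                     (rho * h);
      double b = 1.0 / (1.0 + theta);
      vs[f] *= b;
      beta_v[f] = b;
    }
    for (size_t k = 0; k < screen_uface.size(); ++k) {
      int f = screen_uface[k];
      double theta = dt * (scr_u_avisc[k] +
                           scr_u_ainert[k] * std::fabs(us[f])) / (rho * h);
      us[f] /= (1.0 + theta);
    }
  }

  // ---- pressure projection ------------------------------------------------
  // A p = -(rho h / dt) div*(u~), SPD; matrix-free CG preconditioned by an
  // exact banded Cholesky factorization of the geometry-only matrix A0
  // (all face mobilities 1). A differs from A0 only in the screened rows,
  // so PCG converges in a handful of iterations. Per-cell couplings
  // bW/bE/bS/bN are rebuilt every step (screen mobilities change with |v|).
  std::vector<double> bW, bE, bS, bN, adiag, dic;
  // band ordering: cb = j + i*ny (j fastest), bandwidth ny
  std::vector<double> Lband;   // n x (ny+1), L(c, c-k) at [c*(ny+1)+k]
  std::vector<double> py_, pz_;

  int idb(int i, int j) const { return j + i * ny; }

  void factor_A0() {
    int n = nx * ny, bw = ny, w = bw + 1;
    // A0 entries in band ordering: diagonal, offset 1 (j-1), offset ny (i-1)
    std::vector<double> d0(n, 1.0), o1(n, 0.0), ony(n, 0.0);
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        int cb = idb(i, j);
        if (mask[idc(i, j)] == 0) continue;
        double d = 0;
        if (utype[idu(i, j)] == U_INT) { ony[cb] = -1; d += 1; }
        int te = utype[idu(i + 1, j)];
        if (te == U_INT) d += 1; else if (te == U_OUT) d += 2;
        if (vtype[idv(i, j)] == V_INT) { o1[cb] = -1; d += 1; }
        if (vtype[idv(i, j + 1)] == V_INT) d += 1;
        d0[cb] = (d > 0) ? d : 1.0;
      }
    Lband.assign((size_t)n * w, 0.0);
    for (int c = 0; c < n; ++c) {
      int kmax = std::min(bw, c);
      for (int k = kmax; k >= 1; --k) {
        double s = 0.0;
        if (k == 1) s = o1[c];
        else if (k == bw) s = ony[c];
        for (int m = k + 1; m <= kmax; ++m)
          s -= Lband[(size_t)c * w + m] * Lband[(size_t)(c - k) * w + (m - k)];
        Lband[(size_t)c * w + k] = s / Lband[(size_t)(c - k) * w];
      }
      double s = d0[c];
      for (int m = 1; m <= kmax; ++m) {
        double lv = Lband[(size_t)c * w + m];
        s -= lv * lv;
      }
      if (s <= 0) stop("preconditioner factorization failed");
      Lband[(size_t)c * w] = std::sqrt(s);
    }
    py_.assign(n, 0.0);
    pz_.assign(n, 0.0);
  }

  void build_coeffs() {
    int n = nx * ny;
    bW.assign(n, 0.0); bE.assign(n, 0.0);
    bS.assign(n, 0.0); bN.assign(n, 0.0);
    adiag.assign(n, 1.0); dic.assign(n, 1.0);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = idc(i, j);
        if (mask[c] == 0) continue;
        double d = 0;
        if (utype[idu(i, j)] == U_INT) { bW[c] = 1; d += 1; }
        int te = utype[idu(i + 1, j)];
        if (te == U_INT) { bE[c] = 1; d += 1; }
        else if (te == U_OUT) d += 2;             // p = 0 on the outlet face
        if (vtype[idv(i, j)] == V_INT) {
          bS[c] = beta_v[idv(i, j)]; d += bS[c];
        }
        if (vtype[idv(i, j + 1)] == V_INT) {
          bN[c] = beta_v[idv(i, j + 1)]; d += bN[c];
        }
        adiag[c] = (d > 0) ? d : 1.0;
      }
  }

  void apply_A(const std::vector<double>& x, std::vector<double>& y) const {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int c = idc(i, j);
        if (mask[c] == 0) { y[c] = 0; continue; }
        double off = 0;
        if (bW[c] > 0) off += bW[c] * x[idc(i - 1, j)];
        if (bE[c] > 0) off += bE[c] * x[idc(i + 1, j)];
        if (bS[c] > 0) off += bS[c] * x[idc(i, j - 1)];
        if (bN[c] > 0) off += bN[c] * x[idc(i, j + 1)];
        y[c] = adiag[c] * x[c] - off;
      }
    }
  }

  // z = A0^{-1} r via the banded Cholesky factor (r, z in grid ordering)
  void apply_precond(const std::vector<double>& r, std::vector<double>& z) {
    int n = nx * ny, bw = ny, w = bw + 1;
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j)
        py_[idb(i, j)] = r[idc(i, j)];
    for (int c = 0; c < n; ++c) {
      double s = py_[c];
      int kmax = std::min(bw, c);
      const double* Lr = &Lband[(size_t)c * w];
      for (int k = 1; k <= kmax; ++k) s -= Lr[k] * pz_[c - k];
      pz_[c] = s / Lr[0];
    }
    for (int c = n - 1; c >= 0; --c) {
      double s = pz_[c];
      int kmax = std::min(bw, n - 1 - c);
      for (int k = 1; k <= kmax; ++k)
        s -= Lband[(size_t)(c + k) * w + k] * py_[c + k];
      py_[c] = s / Lband[(size_t)c * w];
    }
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j)
        z[idc(i, j)] = py_[idb(i, j)];
  }

  int project(std::vector<double>& us, std::vector<double>& vs, double dt,
              double tol, int maxit) {
    int n = nx * ny;
    build_coeffs();
    std::vector<double> rhs(n, 0.0);
    double rhsn2 = 0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = idc(i, j);
        if (mask[c] == 0) continue;
        double div = us[idu(i + 1, j)] - us[idu(i, j)] +
                     vs[idv(i, j + 1)] - vs[idv(i, j)];
        rhs[c] = -rho * h / dt * div;
        rhsn2 += rhs[c] * rhs[c];
      }
    if (rhsn2 == 0.0) {
      std::fill(p.begin(), p.end(), 0.0);
      have_prev = false;
      return 0;
    }

    // initial guess: linear extrapolation in time of the pressure field
    std::vector<double> r(n, 0.0), z(n, 0.0), d(n, 0.0), q(n, 0.0);
    if (have_prev) {
      for (int c = 0; c < n; ++c) {
        double pe = 2.0 * p[c] - p_prev[c];
        p_prev[c] = p[c];
        p[c] = pe;
      }
    } else {
      p_prev = p;
      have_prev = true;
    }
    apply_A(p, q);
    for (int c = 0; c < n; ++c) r[c] = (mask[c] ? rhs[c] - q[c] : 0.0);
    double tol2 = tol * tol * rhsn2;
    apply_precond(r, z);
    double rz = 0;
    for (int c = 0; c < n; ++c) rz += r[c] * z[c];
    d = z;
    int it = 0;
    double rn2 = 0; for (int c = 0; c < n; ++c) rn2 += r[c] * r[c];
    while (rn2 > tol2 && it < maxit) {
      apply_A(d, q);
      double dq = 0; for (int c = 0; c < n; ++c) dq += d[c] * q[c];
      if (dq <= 0) break;
      double alpha = rz / dq;
      rn2 = 0;
      for (int c = 0; c < n; ++c) {
        p[c] += alpha * d[c];
        r[c] -= alpha * q[c];
        rn2 += r[c] * r[c];
      }
      apply_precond(r, z);
      double rznew = 0;
      for (int c = 0; c < n; ++c) rznew += r[c] * z[c];
      double bet = rznew / rz; rz = rznew;
      for (int c = 0; c < n; ++c) d[c] = z[c] + bet * d[c];
      ++it;
    }
    if (it >= maxit)
      stop("Poisson tolerance error: CG failed to converge in %d iterations",
           maxit);

    // velocity correction
    double s = dt / (rho * h);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int f = idu(i, j); int t = utype[f];
        if (t == U_INT) us[f] -= s * (p[idc(i, j)] - p[idc(i - 1, j)]);
        else if (t == U_OUT) us[f] -= s * 2.0 * (0.0 - p[idc(nx - 1, j)]);
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int f = idv(i, j);
        if (vtype[f] == V_INT)
          vs[f] -= beta_v[f] * s * (p[idc(i, j)] - p[idc(i, j - 1)]);
      }
    return it;
  }

  double max_divergence() const {
    double m = 0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (mask[idc(i, j)] == 0) continue;
        double div = (u[idu(i + 1, j)] - u[idu(i, j)] +
                      v[idv(i, j + 1)] - v[idv(i, j)]) / h;
        m = std::max(m, std::fabs(div));
      }
    return m;
  }

  double inlet_flux() const {
    double q = 0;
    for (int j = 0; j < ny; ++j)
      if (utype[idu(0, j)] == U_INLET) q += u[idu(0, j)] * h;
    return q;
  }
  double outlet_flux() const {
    double q = 0;
    for (int j = 0; j < ny; ++j)
      if (utype[idu(nx, j)] == U_OUT) q += u[idu(nx, j)] * h;
    return q;
  }
};

}  // namespace

// [[Rcpp::export(name = ".ns_run_cpp")]]
List ns_run_cpp(IntegerMatrix mask, double h, int ny_parent,
                double rho, double mu,
                NumericVector inlet_steady,
                NumericMatrix inlet_harm_re, NumericMatrix inlet_harm_im,
                double omega,
                IntegerVector screen_i, NumericVector screen_s,
                double c1, double c2, double w_screen,
                NumericVector record_times,
                double cfl_safety = 0.4, double cg_tol = 1e-8,
                int cg_maxit = 20000, double dt_max = 5e-3) {
  Solver S;
  S.nx = mask.nrow(); S.ny = mask.ncol(); S.ny_parent = ny_parent;
  S.h = h; S.rho = rho; S.mu = mu; S.nu = mu / rho;
  S.mask.assign(mask.begin(), mask.end());
  S.u.assign((S.nx + 1) * S.ny, 0.0);
  S.v.assign(S.nx * (S.ny + 1), 0.0);
  S.p.assign(S.nx * S.ny, 0.0);
  S.beta_v.assign(S.nx * (S.ny + 1), 1.0);
  S.inlet_steady.assign(inlet_steady.begin(), inlet_steady.end());
  S.K = inlet_harm_re.ncol();
  S.inlet_re.assign(inlet_harm_re.begin(), inlet_harm_re.end());
  S.inlet_im.assign(inlet_harm_im.begin(), inlet_harm_im.end());
  S.omega = omega;
  S.classify();

  // screen faces sit on the wall line j = ny_parent; tangential drag acts
  // on the u-faces of the two cell rows adjacent to the chord (half the
  // layer per row)
  std::map<int, std::pair<double, int> > ufaces;  // face -> (sum s, count)
  for (int k = 0; k < screen_i.size(); ++k) {
    double s = screen_s[k];
    if (s <= 0) continue;
    if (s >= 1) stop("screen solidity must be < 1");
    int ic = screen_i[k];
    int f = S.idv(ic, ny_parent);
    if (S.vtype[f] != V_INT) continue;    // face closed by the geometry
    S.screen_face.push_back(f);
    // viscous: mu * w / kappa(s), kappa = c2 w^2 (1-s)^3 / s^2
    S.scr_avisc.push_back(mu * s * s / (c2 * w_screen * std::pow(1 - s, 3)));
    // inertial: 0.5 rho K(s), K = c1 s / (1-s)^2
    S.scr_ainert.push_back(0.5 * rho * c1 * s / ((1 - s) * (1 - s)));
    // tangential drag only on the sac-side row: the parent main stream runs
    // inside the device lumen and must not feel the screen
    int jr = ny_parent;
    if (jr < S.ny) {
      for (int iu : {ic, ic + 1}) {
        int fu = S.idu(iu, jr);
        if (S.utype[fu] != U_INT) continue;
        auto& e = ufaces[fu];
        e.first += s; e.second += 1;
      }
    }
  }
  for (const auto& e : ufaces) {
    double s = e.second.first / e.second.second;
    S.screen_uface.push_back(e.first);
    S.scr_u_avisc.push_back(mu * s * s /
                            (c2 * w_screen * std::pow(1 - s, 3)));
    S.scr_u_ainert.push_back(0.5 * rho * c1 * s / ((1 - s) * (1 - s)));
  }
  S.factor_A0();

  std::vector<double> rec(record_times.begin(), record_times.end());
  std::sort(rec.begin(), rec.end());
  double t_end = rec.empty() ? 0.0 : rec.back();

  // reference speed for instability detection
  double uref = 0;
  for (int j = 0; j < S.ny; ++j)
    uref = std::max(uref, std::fabs(S.inlet_profile(j, 0.0)));
  for (int k = 0; k < S.K; ++k)
    for (int j = 0; j < S.ny; ++j)
      uref += std::hypot(S.inlet_re[j + k * S.ny], S.inlet_im[j + k * S.ny]) /
              S.ny;
  uref = std::max(uref, 1e-3);

  List snapshots;
  std::vector<double> snap_t, snap_qin, snap_qout, snap_div;
  double t = 0.0;
  size_t next_rec = 0;
  long steps = 0;
  int cg_it_max = 0; double cg_it_total = 0;
  std::vector<double> us, vs;
  double dt_diff = cfl_safety * S.rho * h * h / (4.0 * S.mu);

  while (next_rec < rec.size()) {
    if (t >= rec[next_rec] - 1e-12) {
      // store snapshot
      NumericMatrix um(S.nx + 1, S.ny), vm(S.nx, S.ny + 1), pm(S.nx, S.ny);
      std::copy(S.u.begin(), S.u.end(), um.begin());
      std::copy(S.v.begin(), S.v.end(), vm.begin());
      std::copy(S.p.begin(), S.p.end(), pm.begin());
      snapshots.push_back(List::create(
          _["t"] = t, _["u"] = um, _["v"] = vm, _["p"] = pm));
      snap_t.push_back(t);
      snap_qin.push_back(S.inlet_flux());
      snap_qout.push_back(S.outlet_flux());
      snap_div.push_back(S.max_divergence());
      ++next_rec;
      continue;
    }
    double umax = std::max(S.max_speed(), uref);
    double dt = std::min(cfl_safety * h / umax, dt_diff);
    dt = std::min(dt, dt_max);
    dt = std::min(dt, rec[next_rec] - t);

    S.momentum(us, vs, dt);
    // boundary values at t + dt
    for (int j = 0; j < S.ny; ++j) {
      int fin = S.idu(0, j);
      if (S.utype[fin] == U_INLET) us[fin] = S.inlet_profile(j, t + dt);
      int fout = S.idu(S.nx, j);
      if (S.utype[fout] == U_OUT) us[fout] = us[S.idu(S.nx - 1, j)];
    }
    S.apply_screen(us, vs, dt);
    int it = S.project(us, vs, dt, cg_tol, cg_maxit);
    cg_it_max = std::max(cg_it_max, it); cg_it_total += it;
    S.u.swap(us); S.v.swap(vs);
    t += dt;
    ++steps;
    if (steps % 200 == 0) {
      double m = S.max_speed();
      if (!std::isfinite(m) || m > 100.0 * uref)
        stop("instability error: max speed %g at t = %g (step %ld)",
             m, t, steps);
      Rcpp::checkUserInterrupt();
    }
  }

  return List::create(
      _["snapshots"] = snapshots,
      _["record_t"] = wrap(snap_t),
      _["inlet_flux"] = wrap(snap_qin),
      _["outlet_flux"] = wrap(snap_qout),
      _["max_divergence"] = wrap(snap_div),
      _["steps"] = (double)steps,
      _["cg_it_max"] = cg_it_max, _["cg_it_total"] = cg_it_total,
      _["t_end"] = t_end);
}
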