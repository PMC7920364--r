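// Fractional-step finite-volume core for the transwell invasion model.
//
// State layout: ncell x 11 matrix, columns in the fixed order
//   0 n, 1 N1, 2 N2, 3 rho, 4 C, 5 G, 6 E, 7 D, 8 P, 9 M, 10 A
//
// One macro step of size dt is a Strang split:
//   kinetics dt/2 (implicit trapezoidal rule, damped Newton per cell)
//   transport dt  (explicit upwind diffusion + saturating taxis, CFL
//                  sub-cycled per variable; membrane jump law integrated
//                  exactly per substep)
//   kinetics dt/2
// rho is clamped at zero after each kinetic half step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NF = 11;
enum Field { Fn = 0, FN1, FN2, FRHO, FC, FG, FE, FD, FP, FM, FA };

struct Params {
  double D[NF];                 // diffusivities (rho entry unused)
  double gamma[NF];             // membrane permeabilities (rho unused)
  double r, rE, kE, n0, mu_n;
  int m_growth, l_hill, m_mmp;
  double lam1, lam12, lam2;
  double lamC, muC, lamG, muG, muAG, gsrc;
  double lamE, muE, muED, KD;
  double lamD, muD;
  double lamP, muPM, KM, muP;
  double lamM, muM, lamA, muA;
  double mu_r1, mu_r2;
  double chiE, dE, sE, chiR, dR, sR, chi1, d1, chi2, d2, sC;
};

static Params unpack(const NumericVector& pv, const NumericVector& gam) {
  Params p;
  const double* d = pv.begin();
  // order fixed by the R wrapper (.core_param_vector)
  int k = 0;
  p.D[Fn] = d[k++]; p.D[FN1] = d[k++]; p.D[FN2] = d[k++]; p.D[FRHO] = 0.0;
  p.D[FC] = d[k++]; p.D[FG] = d[k++]; p.D[FE] = d[k++]; p.D[FD] = d[k++];
  p.D[FP] = d[k++]; p.D[FM] = d[k++]; p.D[FA] = d[k++];
  p.r = d[k++]; p.rE = d[k++]; p.kE = d[k++];
  p.m_growth = (int) d[k++]; p.n0 = d[k++]; p.mu_n = d[k++];
  p.lam1 = d[k++]; p.lam12 = d[k++]; p.lam2 = d[k++];
  p.lamC = d[k++]; p.muC = d[k++];
  p.lamG = d[k++]; p.muG = d[k++]; p.muAG = d[k++]; p.gsrc = d[k++];
  p.lamE = d[k++]; p.muE = d[k++]; p.muED = d[k++]; p.KD = d[k++];
  p.l_hill = (int) d[k++];
  p.lamD = d[k++]; p.muD = d[k++];
  p.lamP = d[k++]; p.muPM = d[k++]; p.KM = d[k++];
  p.m_mmp = (int) d[k++]; p.muP = d[k++];
  p.lamM = d[k++]; p.muM = d[k++]; p.lamA = d[k++]; p.muA = d[k++];
  p.mu_r1 = d[k++]; p.mu_r2 = d[k++];
  p.chiE = d[k++]; p.dE = d[k++]; p.sE = d[k++];
  p.chiR = d[k++]; p.dR = d[k++]; p.sR = d[k++];
  p.chi1 = d[k++]; p.d1 = d[k++]; p.chi2 = d[k++]; p.d2 = d[k++];
  p.sC = d[k++];
  for (int v = 0; v < NF; ++v) p.gamma[v] = gam[v];
  return p;
}

static inline double hill(double x, double K, int m, double* dh = nullptr) {
  if (x <= 0.0) { if (dh) *dh = 0.0; return 0.0; }
  double xm = std::pow(x, m), Km = std::pow(K, m);
  double den = Km + xm;
  double H = xm / den;
  if (dh) *dh = m * Km * std::pow(x, m - 1) / (den * den);
  return H;
}

// reaction rates f(u) at one cell; sm/im = S and Omega_I indicators
static void rates(const Params& p, const double* u, double sm, double im,
                  double* f) {
  double hE = hill(u[FE], p.kE, p.m_growth);
  double hD = hill(u[FD], p.KD, p.l_hill);
  double hM = hill(u[FM], p.KM, p.m_mmp);
  f[Fn] = p.r * (1.0 + p.rE * hE) * u[Fn] * (1.0 - u[Fn] / p.n0)
          - p.mu_n * u[FN1] * u[Fn];
  double trans = p.lam12 * u[FG] * u[FN1];
  f[FN1] = p.lam1 * u[FN1] - trans;
  f[FN2] = trans + p.lam2 * u[FN2];
  f[FRHO] = -(p.mu_r1 * u[FE] + p.mu_r2 * u[FP]) * u[Fn] * sm;
  f[FC] = p.lamC * u[Fn] - p.muC * u[FC];
  f[FG] = p.lamG * u[Fn] - p.muG * u[FG] - p.muAG * u[FA] * u[FG] + p.gsrc;
  f[FE] = p.lamE * u[FN2] - p.muE * u[FE] - p.muED * u[FE] * hD;
  f[FD] = p.lamD * im - p.muD * u[FD];
  f[FP] = p.lamP * u[FN2] - p.muPM * u[FP] * hM - p.muP * u[FP];
  f[FM] = p.lamM - p.muM * u[FM];
  f[FA] = p.lamA - p.muA * u[FA];
}

// analytic Jacobian J[i][j] = d f_i / d u_j
static void jacobian(const Params& p, const double* u, double sm,
                     double J[NF][NF]) {
  for (int i = 0; i < NF; ++i)
    for (int j = 0; j < NF; ++j) J[i][j] = 0.0;
  double dhE, dhD, dhM;
  double hE = hill(u[FE], p.kE, p.m_growth, &dhE);
  double hD = hill(u[FD], p.KD, p.l_hill, &dhD);
  double hM = hill(u[FM], p.KM, p.m_mmp, &dhM);
  double gf = p.r * (1.0 + p.rE * hE);
  J[Fn][Fn] = gf * (1.0 - 2.0 * u[Fn] / p.n0) - p.mu_n * u[FN1];
  J[Fn][FN1] = -p.mu_n * u[Fn];
  J[Fn][FE] = p.r * p.rE * dhE * u[Fn] * (1.0 - u[Fn] / p.n0);
  J[FN1][FN1] = p.lam1 - p.lam12 * u[FG];
  J[FN1][FG] = -p.lam12 * u[FN1];
  J[FN2][FN1] = p.lam12 * u[FG];
  J[FN2][FG] = p.lam12 * u[FN1];
  J[FN2][FN2] = p.lam2;
  J[FRHO][Fn] = -(p.mu_r1 * u[FE] + p.mu_r2 * u[FP]) * sm;
  J[FRHO][FE] = -p.mu_r1 * u[Fn] * sm;
  J[FRHO][FP] = -p.mu_r2 * u[Fn] * sm;
  J[FC][Fn] = p.lamC; J[FC][FC] = -p.muC;
  J[FG][Fn] = p.lamG;
  J[FG][FG] = -p.muG - p.muAG * u[FA];
  J[FG][FA] = -p.muAG * u[FG];
  J[FE][FN2] = p.lamE;
  J[FE][FE] = -p.muE - p.muED * hD;
  J[FE][FD] = -p.muED * u[FE] * dhD;
  J[FD][FD] = -p.muD;
  J[FP][FN2] = p.lamP;
  J[FP][FP] = -p.muPM * hM - p.muP;
  J[FP][FM] = -p.muPM * u[FP] * dhM;
  J[FM][FM] = -p.muM;
  J[FA][FA] = -p.muA;
}

// solve A x = b (NF x NF), Gaussian elimination with partial pivoting
static bool lin_solve(double A[NF][NF], double* b, double* x) {
  int piv[NF];
  for (int i = 0; i < NF; ++i) piv[i] = i;
  for (int c = 0; c < NF; ++c) {
    int best = c;
    double mx = std::fabs(A[piv[c]][c]);
    for (int r = c + 1; r < NF; ++r) {
      double v = std::fabs(A[piv[r]][c]);
      if (v > mx) { mx = v; best = r; }
    }
    if (mx < 1e-300) return false;
    std::swap(piv[c], piv[best]);
    double d = A[piv[c]][c];
    for (int r = c + 1; r < NF; ++r) {
      double m = A[piv[r]][c] / d;
      if (m != 0.0) {
        for (int cc = c; cc < NF; ++cc) A[piv[r]][cc] -= m * A[piv[c]][cc];
        b[piv[r]] -= m * b[piv[c]];
      }
    }
  }
  for (int i = NF - 1; i >= 0; --i) {
    double s = b[piv[i]];
    for (int j = i + 1; j < NF; ++j) s -= A[piv[i]][j] * x[j];
    x[i] = s / A[piv[i]][i];
  }
  return true;
}

static inline double inf_norm(const double* v, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m = std::max(m, std::fabs(v[i]));
  return m;
}

// implicit trapezoidal half step at one cell (second order, so two
// consecutive kinetic half steps keep the Strang composition second order);
// returns Newton iterations or -1
static int be_cell(const Params& p, double* u, double dt, double sm,
                   double im, double tol, int maxit) {
  double u0[NF], f0[NF], f[NF], F[NF], J[NF][NF], A[NF][NF], rhs[NF], du[NF],
      utry[NF], Ftry[NF];
  for (int i = 0; i < NF; ++i) u0[i] = u[i];
  double scale = 1.0 + inf_norm(u0, NF);
  double resid = 0.0;
  double hdt = 0.5 * dt;
  rates(p, u0, sm, im, f0);
  rates(p, u, sm, im, f);
  for (int i = 0; i < NF; ++i) F[i] = u[i] - u0[i] - hdt * (f0[i] + f[i]);
  resid = inf_norm(F, NF);
  int it = 0;
  while (resid > tol * scale) {
    if (++it > maxit) return -1;
    jacobian(p, u, sm, J);
    for (int i = 0; i < NF; ++i) {
      for (int j = 0; j < NF; ++j) A[i][j] = -hdt * J[i][j];
      A[i][i] += 1.0;
      rhs[i] = -F[i];
    }
    if (!lin_solve(A, rhs, du)) return -1;
    // damped update: halve until the residual decreases
    double alpha = 1.0;
    bool ok = false;
    for (int h = 0; h < 12; ++h) {
      for (int i = 0; i < NF; ++i) utry[i] = u[i] + alpha * du[i];
      rates(p, utry, sm, im, f);
      for (int i = 0; i < NF; ++i)
        Ftry[i] = utry[i] - u0[i] - hdt * (f0[i] + f[i]);
      double rtry = inf_norm(Ftry, NF);
      if (rtry < resid || rtry <= tol * scale) {
        for (int i = 0; i < NF; ++i) { u[i] = utry[i]; F[i] = Ftry[i]; }
        resid = rtry;
        ok = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!ok) return -1;
  }
  return it;
}

// kinetics half step over all cells; returns max Newton iterations or -1
static int kinetics_half(const Params& p, NumericMatrix& U, double dt,
                         const NumericVector& smask, const NumericVector& imask,
                         double tol, int maxit) {
  int nc = U.nrow();
  int worst = 0;
  std::vector<double> u(NF);
  for (int c = 0; c < nc; ++c) {
    for (int v = 0; v < NF; ++v) u[v] = U(c, v);
    int it = be_cell(p, u.data(), dt, smask[c], imask[c], tol, maxit);
    if (it < 0) return -1;
    worst = std::max(worst, it);
    for (int v = 0; v < NF; ++v) {
      double val = u[v];
      if (val < 0.0) val = 0.0;  // quasi-positive kinetics; clamp roundoff
      U(c, v) = val;
    }
  }
  return worst;
}

// explicit transport of one variable over macro step dt with sub-cycling;
// w = face velocities (size nc+1, exterior and membrane entries zero)
static void transport_var(NumericMatrix& U, int v, double Dv, double gam,
                          const std::vector<double>& w, double dt, double h,
                          int mf, double cfl) {
  int nc = U.nrow();
  double wmax = 0.0;
  for (int f = 1; f < nc; ++f) wmax = std::max(wmax, std::fabs(w[f]));
  double rate = 2.0 * Dv / (h * h) + wmax / h;
  int nsub = 1;
  if (rate > 0.0) {
    double dts = cfl / rate;
    nsub = (int) std::ceil(dt / dts - 1e-12);
    if (nsub < 1) nsub = 1;
  }
  double dts = dt / nsub;
  std::vector<double> u(nc), flux(nc + 1, 0.0);
  for (int c = 0; c < nc; ++c) u[c] = U(c, v);
  double relax = (gam > 0.0) ? std::exp(-2.0 * gam * dts / h) : 1.0;
  for (int s = 0; s < nsub; ++s) {
    for (int f = 1; f < nc; ++f) {
      if (f == mf) { flux[f] = 0.0; continue; }
      double fl = -Dv * (u[f] - u[f - 1]) / h;
      double wf = w[f];
      if (wf != 0.0) fl += wf * (wf > 0.0 ? u[f - 1] : u[f]);
      flux[f] = fl;
    }
    for (int c = 0; c < nc; ++c) u[c] -= dts * (flux[c + 1] - flux[c]) / h;
    // membrane jump law J = gamma (u_lower - u_upper), integrated exactly
    // over the substep (pairwise exponential relaxation; conservative and
    // stable for any gamma)
    if (gam > 0.0) {
      double a = u[mf - 1], b = u[mf];
      double mean = 0.5 * (a + b), half = 0.5 * (a - b) * relax;
      u[mf - 1] = mean + half;
      u[mf] = mean - half;
    }
  }
  for (int c = 0; c < nc; ++c) U(c, v) = u[c];
}

// face velocities for the taxis terms of variable v, from frozen fields
static void taxis_velocity(const Params& p, const NumericMatrix& U, int v,
                           const NumericVector& smask, double h, int mf,
                           std::vector<double>& w) {
  int nc = U.nrow();
  w.assign(nc + 1, 0.0);
  if (v == Fn) {
    for (int f = 1; f < nc; ++f) {
      if (f == mf) continue;
      double gEv = (U(f, FE) - U(f - 1, FE)) / h;
      double wv = p.chiE * gEv / (p.dE + p.sE * std::fabs(gEv));
      if (smask[f - 1] > 0 || smask[f] > 0) {
        double gR = (U(f, FRHO) - U(f - 1, FRHO)) / h;
        wv += p.chiR * gR / (p.dR + p.sR * std::fabs(gR));
      }
      w[f] = wv;
    }
  } else if (v == FN1 || v == FN2) {
    double chi = (v == FN1) ? p.chi1 : p.chi2;
    double del = (v == FN1) ? p.d1 : p.d2;
    for (int f = 1; f < nc; ++f) {
      if (f == mf) continue;
      double gC = (U(f, FC) - U(f - 1, FC)) / h;
      w[f] = chi * gC / (del + p.sC * std::fabs(gC));
    }
  }
}

static void transport_step(const Params& p, NumericMatrix& U, double dt,
                           const NumericVector& smask, double h, int mf,
                           double cfl) {
  // taxis velocities frozen at the start of the transport step
  std::vector<double> w;
  for (int v = 0; v < NF; ++v) {
    if (v == FRHO) continue;
    taxis_velocity(p, U, v, smask, h, mf, w);
    transport_var(U, v, p.D[v], p.gamma[v], w, dt, h, mf, cfl);
  }
}

// one Strang step on a working copy; returns max Newton iters or -1
static int strang_step(const Params& p, NumericMatrix& U, double dt,
                       const NumericVector& smask, const NumericVector& imask,
                       double h, int mf, double tol, int maxit, double cfl) {
  int i1 = kinetics_half(p, U, 0.5 * dt, smask, imask, tol, maxit);
  if (i1 < 0) return -1;
  transport_step(p, U, dt, smask, h, mf, cfl);
  int i2 = kinetics_half(p, U, 0.5 * dt, smask, imask, tol, maxit);
  if (i2 < 0) return -1;
  return std::max(i1, i2);
}

// [[Rcpp::export(name = ".core_step")]]
List core_step(NumericMatrix U, double dt, NumericVector par,
               NumericVector gamma, NumericVector smask, NumericVector imask,
               double h, int membrane_face, double newton_tol,
               int newton_maxit, double cfl) {
  Params p = unpack(par, gamma);
  NumericMatrix W = clone(U);
  int mf = membrane_face - 1;  // 0-based face index
  int it = strang_step(p, W, dt, smask, imask, h, mf, newton_tol,
                       newton_maxit, cfl);
  return List::create(_["state"] = W, _["newton_iters"] = it,
                      _["ok"] = (it >= 0));
}

// [[Rcpp::export(name = ".core_run")]]
List core_run(NumericMatrix U0, double t0, NumericVector out_times,
              NumericVector par, NumericVector gamma, NumericVector smask,
              NumericVector imask, double h, int membrane_face,
              double dt_init, double dt_min, double dt_max, double newton_tol,
              int newton_maxit, double cfl, int grow_after,
              double grow_factor, double blowup_warn) {
  Params p = unpack(par, gamma);
  int mf = membrane_face - 1;
  int nout = out_times.size();
  NumericMatrix U = clone(U0);
  List snaps(nout);
  double t = t0, dt = dt_init;
  long steps = 0, rejections = 0;
  int streak = 0, iout = 0;
  bool blowup = false;
  while (iout < nout && out_times[iout] <= t + 1e-12) {
    snaps[iout] = clone(U);
    ++iout;
  }
  // the step sequence depends only on t_end, never on the output schedule:
  // intermediate snapshots are dense output (linear interpolation inside the
  // containing step), so refining the schedule cannot perturb the trajectory
  double t_end = out_times[nout - 1];
  while (t < t_end - 1e-12) {
    double dt_try = std::min(dt, t_end - t);
    NumericMatrix W = clone(U);
    int it = strang_step(p, W, dt_try, smask, imask, h, mf, newton_tol,
                         newton_maxit, cfl);
    if (it < 0) {
      ++rejections;
      streak = 0;
      dt *= 0.5;
      if (dt < dt_min) {
        return List::create(_["error"] = true, _["t_reached"] = t,
                            _["state"] = U, _["steps"] = (double) steps,
                            _["rejections"] = (double) rejections);
      }
      continue;
    }
    double t_new = t + dt_try;
    while (iout < nout && out_times[iout] <= t_new + 1e-12) {
      double w = (out_times[iout] - t) / dt_try;
      if (w > 1.0 - 1e-12) {
        snaps[iout] = clone(W);
      } else {
        NumericMatrix S(U.nrow(), NF);
        for (int i = 0; i < U.nrow(); ++i)
          for (int v = 0; v < NF; ++v)
            S(i, v) = (1.0 - w) * U(i, v) + w * W(i, v);
        snaps[iout] = S;
      }
      ++iout;
    }
    U = W;
    t = t_new;
    ++steps;
    if (!blowup) {
      double mx = 0.0;
      for (int i = 0; i < U.nrow(); ++i)
        for (int v = 0; v < NF; ++v) mx = std::max(mx, std::fabs(U(i, v)));
      if (mx > blowup_warn) blowup = true;
    }
    if (it <= 5) {
      if (++streak >= grow_after) {
        dt = std::min(dt * grow_factor, dt_max);
        streak = 0;
      }
    } else {
      streak = 0;
    }
    if (steps % 256 == 0) Rcpp::checkUserInterrupt();
  }
  while (iout < nout) { snaps[iout] = clone(U); ++iout; }
  return List::create(_["error"] = false, _["snapshots"] = snaps,
                      _["times"] = out_times, _["steps"] = (double) steps,
                      _["rejections"] = (double) rejections,
                      _["blowup_warning"] = blowup);
}
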