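// Fixed-step integration core for the dendritic timing model.
//
// State vector layout (concentrations in uM, time in s):
//   0 x     pool calcium
//   1 y     cytosolic (oscillator) calcium
//   2 AC    active adenylyl cyclase
//   3 cAMP
//   4 PKA   active protein kinase A
//   5 PDE   active phosphodiesterase
//   6 RGS   active RGS fraction
//   7 z     RGS-gating auxiliary variable
//
// Stimulus inputs (Gi, Gs, the synaptic-calcium window) are prescribed
// functions of the time since CS / US onset and of the end-of-step state;
// the backward-Euler solve evaluates them at the step's end time.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSP = 8;

// Canonical parameter order; kept in lock-step with param_vector() on the
// R side.
enum Par {
  P_k1 = 0, P_k2, P_alpha_store, P_beta, P_gamma, P_h, P_n, P_B_Ca,
  P_pka_gain, P_x_init_on_CS, P_ca_window,
  P_gi_a, P_gi_b, P_gi_rise_window, P_gi_off_time,
  P_r1_bl, P_r_cag, P_K_ca_AC, P_K_Gi, P_r2_bl, P_r_ca,
  P_k8, P_k10, P_km, P_ka7, P_k7,
  P_k13, P_k14, P_km2, P_k15,
  P_r5, P_r6, P_z_threshold, P_r3_bl, P_K_ca_RGS, P_r4,
  P_K_g, P_gs_amplitude, P_gs_window,
  P_AC_total, P_PKA_total, P_PDE_total,
  NPAR
};

static inline double cube(double v) { return v * v * v; }

static inline double f_cicr(double y, double h, double n) {
  if (y <= 0.0) return 0.0;
  double yn = std::pow(y, n), hn = std::pow(h, n);
  return yn / (yn + hn);
}

// Gi transient: exponential growth for gi_rise_window, held until
// gi_off_time, zero afterwards (and before any CS).
static inline double gi_input(double tcs, const double* p) {
  if (!R_finite(tcs) || tcs < 0.0) return 0.0;
  if (tcs >= p[P_gi_off_time]) return 0.0;
  double t = std::min(tcs, p[P_gi_rise_window]);
  return p[P_gi_a] * std::exp(p[P_gi_b] * t);
}

// Gs generation window after US, suppressed by active RGS.
static inline double gs_input(double tus, double RGS, const double* p) {
  if (!R_finite(tus) || tus < 0.0 || tus > p[P_gs_window]) return 0.0;
  double kg3 = cube(p[P_K_g]);
  double r = RGS > 0.0 ? RGS : 0.0;
  return p[P_gs_amplitude] * kg3 / (kg3 + cube(r));
}

// Synaptic calcium read-out: basal outside the post-CS window, PKA-amplified
// oscillator calcium inside it.
static inline double eff_calcium(double y, double PKA, double tcs,
                                 const double* p) {
  if (!R_finite(tcs) || tcs < 0.0 || tcs > p[P_ca_window]) return p[P_B_Ca];
  return (1.0 + p[P_pka_gain] * PKA) * y;
}

// Full right-hand side. alpha_override: -1 evaluates the z switch from the
// state, 0/1 force the switch branch (used to settle the implicit solve when
// the discontinuity sits inside the step).
static void model_rhs(const double* s, double tcs, double tus,
                      const double* p, double* ds, int alpha_override = -1) {
  const double x = s[0], y = s[1], AC = s[2], cAMP = s[3], PKA = s[4],
               PDE = s[5], RGS = s[6], z = s[7];

  const double Ca = eff_calcium(y, PKA, tcs, p);
  const double Gi = gi_input(tcs, p);
  const double Gs = gs_input(tus, RGS, p);

  // Calcium store (Somogyi-Stucki oscillator)
  const double fy = f_cicr(y, p[P_h], p[P_n]);
  const double cicr = p[P_alpha_store] * fy * x;
  ds[0] = p[P_k1] * y - p[P_k2] * x - cicr;
  ds[1] = p[P_k2] * x - p[P_k1] * y + cicr + p[P_gamma] - p[P_beta] * y;

  // Adenylyl cyclase: synergistic activation by Ca and Gs, inhibited by Gi
  const double ca3 = cube(Ca);
  const double r1 = p[P_r1_bl] +
    p[P_r_cag] * Gs * ca3 / (cube(p[P_K_ca_AC]) + ca3) *
    p[P_K_Gi] / (p[P_K_Gi] + Gi);
  const double r2 = p[P_r2_bl] + p[P_r_ca] * Ca;
  ds[2] = r1 * (p[P_AC_total] - AC) - r2 * AC;

  // cAMP / PKA / PDE
  ds[3] = p[P_k8] * AC - p[P_k10] * PDE * cAMP / (p[P_km] + cAMP);
  ds[4] = p[P_ka7] * (p[P_PKA_total] - PKA) * cAMP - p[P_k7] * PKA;
  const double PDEi = p[P_PDE_total] - PDE;
  ds[5] = p[P_k13] + p[P_k14] * PKA * PDEi / (p[P_km2] + PDEi) -
          p[P_k15] * PDE;

  // RGS switch and dynamics
  double alpha;
  if (alpha_override >= 0) alpha = alpha_override;
  else alpha = (z > p[P_z_threshold]) ? 1.0 : 0.0;
  ds[6] = (p[P_r5] + alpha) * (1.0 - RGS) - p[P_r6] * RGS;
  const double r3 = p[P_r3_bl] * Ca * Ca / (p[P_K_ca_RGS] + Ca);
  ds[7] = r3 * (1.0 - z) - p[P_r4] * z;
}

// ' @keywords internal
// [[Rcpp::export(rng = false)]]
NumericVector cpp_model_rhs(NumericVector state, double t_since_cs,
                            double t_since_us, NumericVector par) {
  if (state.size() != NSP) stop("state must have %d entries", NSP);
  if (par.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  NumericVector out(NSP);
  model_rhs(REAL(state), t_since_cs, t_since_us, REAL(par), REAL(out));
  return out;
}

// Solve an 8x8 dense linear system in place (partial pivoting).
static bool solve8(double A[NSP][NSP], double b[NSP]) {
  int piv[NSP];
  for (int i = 0; i < NSP; ++i) piv[i] = i;
  for (int c = 0; c < NSP; ++c) {
    int best = c;
    double mx = std::fabs(A[c][c]);
    for (int r = c + 1; r < NSP; ++r)
      if (std::fabs(A[r][c]) > mx) { mx = std::fabs(A[r][c]); best = r; }
    if (mx < 1e-300) return false;
    if (best != c) {
      for (int k = 0; k < NSP; ++k) std::swap(A[c][k], A[best][k]);
      std::swap(b[c], b[best]);
    }
    for (int r = c + 1; r < NSP; ++r) {
      double m = A[r][c] / A[c][c];
      if (m == 0.0) continue;
      for (int k = c; k < NSP; ++k) A[r][k] -= m * A[c][k];
      b[r] -= m * b[c];
    }
  }
  for (int r = NSP - 1; r >= 0; --r) {
    double acc = b[r];
    for (int k = r + 1; k < NSP; ++k) acc -= A[r][k] * b[k];
    b[r] = acc / A[r][r];
  }
  return true;
}

// One backward-Euler step: solve s1 = s0 + dt * f(s1, t_end).
// Damped fixed-point iteration first; Newton with finite-difference
// Jacobian as a fallback. The z switch is evaluated from the running
// iterate and frozen late in the iteration so a flip inside the step is
// accepted without hysteresis.
static void be_step(const double* s0, double tcs_end, double tus_end,
                    const double* p, double dt, double tol, int max_iter,
                    double t_now, double* s1) {
  double cur[NSP], nxt[NSP], ds[NSP];
  for (int i = 0; i < NSP; ++i) cur[i] = s0[i];

  int freeze_after = max_iter / 2;
  int alpha_frozen = -1;
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    if (it == freeze_after)
      alpha_frozen = (cur[7] > p[P_z_threshold]) ? 1 : 0;
    model_rhs(cur, tcs_end, tus_end, p, ds, alpha_frozen);
    double err = 0.0;
    for (int i = 0; i < NSP; ++i) {
      nxt[i] = s0[i] + dt * ds[i];
      double e = std::fabs(nxt[i] - cur[i]) / (1.0 + std::fabs(nxt[i]));
      if (e > err) err = e;
    }
    for (int i = 0; i < NSP; ++i) cur[i] = nxt[i];
    if (err < tol) { converged = true; break; }
  }

  if (!converged) {
    // Newton on G(s) = s - s0 - dt f(s); switch branch frozen at the
    // current iterate.
    alpha_frozen = (cur[7] > p[P_z_threshold]) ? 1 : 0;
    for (int it = 0; it < max_iter; ++it) {
      double g0[NSP], A[NSP][NSP], b[NSP];
      model_rhs(cur, tcs_end, tus_end, p, ds, alpha_frozen);
      double err = 0.0;
      for (int i = 0; i < NSP; ++i) {
        g0[i] = cur[i] - s0[i] - dt * ds[i];
        err = std::max(err, std::fabs(g0[i]) / (1.0 + std::fabs(cur[i])));
      }
      if (err < tol) { converged = true; break; }
      for (int j = 0; j < NSP; ++j) {
        double pert[NSP], dsp[NSP];
        double hstep = 1e-7 * (1.0 + std::fabs(cur[j]));
        for (int i = 0; i < NSP; ++i) pert[i] = cur[i];
        pert[j] += hstep;
        model_rhs(pert, tcs_end, tus_end, p, dsp, alpha_frozen);
        for (int i = 0; i < NSP; ++i)
          A[i][j] = (i == j ? 1.0 : 0.0) - dt * (dsp[i] - ds[i]) / hstep;
      }
      for (int i = 0; i < NSP; ++i) b[i] = -g0[i];
      if (!solve8(A, b)) break;
      for (int i = 0; i < NSP; ++i) cur[i] += b[i];
    }
  }

  if (!converged)
    stop("backward-Euler solve did not converge at t = %.6f s", t_now);
  for (int i = 0; i < NSP; ++i) s1[i] = cur[i];
}

// Classical explicit RK4 step (cross-validation oracle); stimulus inputs are
// evaluated at the stage times.
static void rk4_step(const double* s0, double tcs0, double tus0,
                     const double* p, double dt, double* s1) {
  double k1[NSP], k2[NSP], k3[NSP], k4[NSP], tmp[NSP];
  double th = dt / 2.0;
  auto adv = [&](double t) { return R_finite(t) ? t : t; };
  (void)adv;
  model_rhs(s0, tcs0, tus0, p, k1);
  for (int i = 0; i < NSP; ++i) tmp[i] = s0[i] + th * k1[i];
  model_rhs(tmp, tcs0 + th, tus0 + th, p, k2);
  for (int i = 0; i < NSP; ++i) tmp[i] = s0[i] + th * k2[i];
  model_rhs(tmp, tcs0 + th, tus0 + th, p, k3);
  for (int i = 0; i < NSP; ++i) tmp[i] = s0[i] + dt * k3[i];
  model_rhs(tmp, tcs0 + dt, tus0 + dt, p, k4);
  for (int i = 0; i < NSP; ++i)
    s1[i] = s0[i] + dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static void check_invariants(const double* s, const double* p, double t) {
  const double tol = 1e-6;
  const char* names[NSP] = {"x", "y", "AC", "cAMP", "PKA", "PDE", "RGS", "z"};
  for (int i = 0; i < NSP; ++i)
    if (s[i] < -tol)
      stop("invariant violation at t = %.6f s: %s = %g < 0", t, names[i], s[i]);
  if (s[2] > p[P_AC_total] + tol)
    stop("invariant violation at t = %.6f s: AC exceeds AC_total", t);
  if (s[4] > p[P_PKA_total] + tol)
    stop("invariant violation at t = %.6f s: PKA exceeds PKA_total", t);
  if (s[5] > p[P_PDE_total] + tol)
    stop("invariant violation at t = %.6f s: PDE exceeds PDE_total", t);
  if (s[6] > 1.0 + tol || s[7] > 1.0 + tol)
    stop("invariant violation at t = %.6f s: RGS/z above 1", t);
}

// ' @keywords internal
// [[Rcpp::export(rng = false)]]
List cpp_integrate(NumericVector state0, NumericVector par, double duration,
                   double dt, NumericVector cs_times, NumericVector us_times,
                   int method, double newton_tol, int newton_max_iter,
                   int record_stride, double t_since_cs0, double t_since_us0,
                   double t0) {
  if (state0.size() != NSP) stop("state must have %d entries", NSP);
  if (par.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  if (dt <= 0.0) stop("dt must be positive");
  if (duration <= 0.0) stop("duration must be positive");
  if (record_stride < 1) stop("record_stride must be >= 1");

  const double* p = REAL(par);
  long nsteps = (long)std::llround(duration / dt);
  if (std::fabs(nsteps * dt - duration) > 1e-9 * std::max(1.0, duration))
    stop("duration must be an integer multiple of dt");

  // Align events to the step grid.
  std::vector<long> cs_idx(cs_times.size()), us_idx(us_times.size());
  for (int i = 0; i < cs_times.size(); ++i) {
    double rel = cs_times[i] - t0;
    long k = (long)std::llround(rel / dt);
    if (k < 0 || k > nsteps || std::fabs(k * dt - rel) > 1e-9)
      stop("CS time %g does not fall on the integration grid", cs_times[i]);
    cs_idx[i] = k;
  }
  for (int i = 0; i < us_times.size(); ++i) {
    double rel = us_times[i] - t0;
    long k = (long)std::llround(rel / dt);
    if (k < 0 || k > nsteps || std::fabs(k * dt - rel) > 1e-9)
      stop("US time %g does not fall on the integration grid", us_times[i]);
    us_idx[i] = k;
  }

  long nsamp = nsteps / record_stride + 1;
  bool extra_final = (nsteps % record_stride) != 0;
  if (extra_final) ++nsamp;

  NumericVector times(nsamp);
  NumericMatrix rec(nsamp, 11);  // x y Ca Gi Gs AC cAMP PKA PDE RGS z
  IntegerVector ev(nsamp);       // 0 none, 1 CS, 2 US, 3 both

  double s[NSP], s1[NSP];
  for (int i = 0; i < NSP; ++i) s[i] = state0[i];
  double tcs = t_since_cs0, tus = t_since_us0;
  const double y_rest = p[P_beta] > 0.0 ? p[P_gamma] / p[P_beta] : 0.0;

  size_t csp = 0, usp = 0;
  long samp = 0;

  auto record = [&](long k, int event) {
    double t = t0 + k * dt;
    times[samp] = t;
    rec(samp, 0) = s[0];
    rec(samp, 1) = s[1];
    rec(samp, 2) = eff_calcium(s[1], s[4], tcs, p);
    rec(samp, 3) = gi_input(tcs, p);
    rec(samp, 4) = gs_input(tus, s[6], p);
    rec(samp, 5) = s[2];
    rec(samp, 6) = s[3];
    rec(samp, 7) = s[4];
    rec(samp, 8) = s[5];
    rec(samp, 9) = s[6];
    rec(samp, 10) = s[7];
    ev[samp] = event;
    ++samp;
  };

  for (long k = 0; k <= nsteps; ++k) {
    int event = 0;
    while (csp < cs_idx.size() && cs_idx[csp] == k) {
      s[0] = p[P_x_init_on_CS];
      s[1] = y_rest;
      tcs = 0.0;
      event |= 1;
      ++csp;
    }
    while (usp < us_idx.size() && us_idx[usp] == k) {
      tus = 0.0;
      event |= 2;
      ++usp;
    }

    if (k % record_stride == 0 || k == nsteps) record(k, event);
    if (k == nsteps) break;

    double tcs_end = R_finite(tcs) ? tcs + dt : tcs;
    double tus_end = R_finite(tus) ? tus + dt : tus;
    if (method == 0)
      be_step(s, tcs_end, tus_end, p, dt, newton_tol, newton_max_iter,
              t0 + k * dt, s1);
    else
      rk4_step(s, tcs, tus, p, dt, s1);
    for (int i = 0; i < NSP; ++i) s[i] = s1[i];
    tcs = tcs_end;
    tus = tus_end;
    check_invariants(s, p, t0 + (k + 1) * dt);
  }

  NumericVector fin(NSP);
  for (int i = 0; i < NSP; ++i) fin[i] = s[i];
  return List::create(_["time"] = times, _["rec"] = rec, _["event"] = ev,
                      _["state"] = fin, _["t_since_cs"] = tcs,
                      _["t_since_us"] = tus, _["t_end"] = t0 + nsteps * dt);
}
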