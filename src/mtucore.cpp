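#include <Rcpp.h>
#include "mtu.h"

using namespace Rcpp;

static mtu::Params as_params(const NumericVector& p) {
  mtu::Params q;
  q.lo = p["lo"]; q.alpha_o = p["alpha_o"]; q.fo = p["fo"];
  q.ls = p["ls"]; q.vmax = p["vmax"]; q.eo = p["eo"];
  q.beta = p["beta"]; q.beta_t = p["beta_t"]; q.r = p["r"];
  return q;
}

// ---- characteristic curves (vectorized) -------------------------------

// [[Rcpp::export]]
NumericVector cpp_fl(NumericVector l) {
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) out[i] = mtu::fl(l[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dfl(NumericVector l) {
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) out[i] = mtu::dfl(l[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fv(NumericVector v) {
  NumericVector out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = mtu::fv(v[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dfv(NumericVector v) {
  NumericVector out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = mtu::dfv(v[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fv_inv(NumericVector f) {
  NumericVector out(f.size());
  for (R_xlen_t i = 0; i < f.size(); ++i) out[i] = mtu::fv_inv(f[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fpe(NumericVector l) {
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) out[i] = mtu::fpe(l[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dfpe(NumericVector l) {
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) out[i] = mtu::dfpe(l[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ft(NumericVector e, double eo) {
  NumericVector out(e.size());
  for (R_xlen_t i = 0; i < e.size(); ++i) out[i] = mtu::ft(e[i], eo);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dft(NumericVector e, double eo) {
  NumericVector out(e.size());
  for (R_xlen_t i = 0; i < e.size(); ++i) out[i] = mtu::dft(e[i], eo);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ft_energy(NumericVector e, double eo) {
  NumericVector out(e.size());
  for (R_xlen_t i = 0; i < e.size(); ++i) out[i] = mtu::ft_energy(e[i], eo);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ft_inv(NumericVector f, double eo) {
  NumericVector out(f.size());
  for (R_xlen_t i = 0; i < f.size(); ++i) out[i] = mtu::ft_inv(f[i], eo);
  return out;
}

// ---- static equilibrium ----------------------------------------------

// [[Rcpp::export]]
double cpp_static_fiber_length(double a, double lP, NumericVector params) {
  return mtu::static_fiber_length(a, lP, as_params(params));
}

// [[Rcpp::export]]
double cpp_static_force(double a, double lP, NumericVector params) {
  return mtu::static_force(a, lP, as_params(params));
}

// [[Rcpp::export]]
NumericVector cpp_static_force_sweep(double a, NumericVector lP,
                                     NumericVector params) {
  const mtu::Params p = as_params(params);
  NumericVector out(lP.size());
  for (R_xlen_t i = 0; i < lP.size(); ++i)
    out[i] = mtu::static_force(a, lP[i], p);
  return out;
}

// ---- damped-equilibrium fiber velocity --------------------------------

// [[Rcpp::export]]
List cpp_solve_vtil(double a, double l_ce, double lP, double vP,
                    NumericVector params) {
  const mtu::Params p = as_params(params);
  bool clamped = false;
  const double vtil = mtu::solve_vtil(a, l_ce, lP, vP, p, &clamped);
  // normalized force-balance residual (units of fo)
  const double ca = mtu::cos_alpha(l_ce, p);
  const double e = (lP - l_ce * ca - p.ls) / p.ls;
  double bT = 0.0;
  if (p.beta_t > 0.0) bT = p.beta_t * (p.fo / p.ls) * mtu::dft(e, p.eo) / p.fo;
  const double vT = vP - vtil * p.Vmax() / ca;
  const double resid = mtu::ce_force_along(a, l_ce, vtil, p) -
                       (mtu::ft(e, p.eo) + bT * vT);
  return List::create(_["vtil"] = vtil, _["resid"] = resid,
                      _["clamped"] = clamped);
}

// ---- trial integration -------------------------------------------------

namespace {

struct Kinematics {
  // piecewise constant-acceleration segments: start time, theta0, omega0, acc
  std::vector<double> t0, th0, om0, ac;
  void eval(double t, double* theta, double* omega) const {
    size_t i = t0.size() - 1;
    while (i > 0 && t < t0[i]) --i;
    const double dt = t - t0[i];
    *theta = th0[i] + om0[i] * dt + 0.5 * ac[i] * dt * dt;
    *omega = om0[i] + ac[i] * dt;
  }
};

// State: y[0] activation, y[1] fiber length (elastic), y[2] cumulative CE
// work (integrated with the state so energy closure inherits the
// integrator tolerance).
struct Deriv {
  const mtu::Params* p;
  const Kinematics* kin;
  double lP_ref, t_u, u_before, u_after;
  long clamp_count = 0;

  double u_at(double t) const { return t < t_u ? u_before : u_after; }

  void operator()(double t, const double* y, double* dy) {
    const double u = u_at(t);
    const double a = std::min(std::max(y[0], 0.0), 1.0);
    const double tau = (u > a) ? 0.015 : 0.050;
    dy[0] = (u - a) / tau;
    double theta, omega;
    kin->eval(t, &theta, &omega);
    const double lP = lP_ref - p->r * theta;
    const double vP = -p->r * omega;
    if (!p->rigid()) {
      bool clamped = false;
      const double vtil = mtu::solve_vtil(a, y[1], lP, vP, *p, &clamped);
      if (clamped) ++clamp_count;
      dy[1] = vtil * p->Vmax();
      const double ca = mtu::cos_alpha(y[1], *p);
      const double e = (lP - y[1] * ca - p->ls) / p->ls;
      double ftot = p->fo * mtu::ft(e, p->eo);
      if (p->beta_t > 0.0) {
        const double KT = (p->fo / p->ls) * mtu::dft(e, p->eo);
        ftot += p->beta_t * KT * (vP - dy[1] / ca);
      }
      dy[2] = ftot * (-dy[1] / ca);           // F_T * (-v_CE_AT)
    } else {
      const double x = std::max(lP - p->ls, 1e-9);
      const double h = p->h();
      const double l_ce = std::sqrt(x * x + h * h);
      const double ca = x / l_ce;
      const double vtil = vP * ca / p->Vmax();
      const double ftot = p->fo * mtu::ce_force_along(a, l_ce, vtil, *p);
      dy[1] = 0.0;
      dy[2] = ftot * (-vP);                   // v_CE_AT = vP for rigid
    }
  }
};

// Dormand-Prince 5(4) with FSAL, stepping exactly onto requested times.
void dopri5(Deriv& f, double* y, int n, double t0, double t1,
            double rtol, double atol) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  if (t1 <= t0) return;
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], yt[3], y5[3];
  double t = t0;
  double h = std::min(1e-4, t1 - t0);
  f(t, y, k1);
  int reject_guard = 0;
  while (t < t1 - 1e-14) {
    if (t + h > t1) h = t1 - t;
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    f(t + c2 * h, yt, k2);
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    f(t + c3 * h, yt, k3);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    f(t + c4 * h, yt, k4);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    f(t + c5 * h, yt, k5);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    f(t + h, yt, k6);
    for (int i = 0; i < n; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    f(t + h, y5, k7);
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      err += (ei / sc) * (ei / sc);
    }
    err = std::sqrt(err / n);
    if (err <= 1.0 || h <= 1e-12) {
      t += h;
      for (int i = 0; i < n; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
      reject_guard = 0;
    } else if (++reject_guard > 1000) {
      Rcpp::stop("integrator failed to find an acceptable step at t=%g", t);
    }
    const double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    h *= std::min(5.0, std::max(0.2, fac));
    h = std::min(h, 2e-3);   // resolve the 1 kHz output clock comfortably
    if (h < 1e-12) h = 1e-12;
  }
}

}  // namespace

// Integrate one trial.  `segments` is a matrix with columns
// (t_start, theta0_rad, omega0_rad_s, acc_rad_s2); excitation steps from
// u_before to u_after at t_u.  Output rows at `times` (sorted, starting
// at 0); derived channels are recomputed from the state at each sample so
// the force-balance residual column reflects the emitted samples.
// [[Rcpp::export]]
List cpp_simulate(NumericVector params, NumericVector times,
                  NumericMatrix segments, double t_u, double u_before,
                  double u_after, double a0, double lce0,
                  double lP_ref, double rtol, double atol) {
  const mtu::Params p = as_params(params);
  Kinematics kin;
  for (int i = 0; i < segments.nrow(); ++i) {
    kin.t0.push_back(segments(i, 0));
    kin.th0.push_back(segments(i, 1));
    kin.om0.push_back(segments(i, 2));
    kin.ac.push_back(segments(i, 3));
  }
  Deriv f;
  f.p = &p; f.kin = &kin; f.lP_ref = lP_ref;
  f.t_u = t_u; f.u_before = u_before; f.u_after = u_after;

  const int nt = times.size();
  const int ncol = 17;
  NumericMatrix out(nt, ncol);
  double y[3] = {a0, lce0, 0.0};

  // breakpoints where the RHS is non-smooth: segment starts and t_u
  std::vector<double> bp(kin.t0);
  bp.push_back(t_u);

  for (int i = 0; i < nt; ++i) {
    if (i > 0) {
      double t = times[i - 1];
      const double tend = times[i];
      // split on any interior breakpoint
      std::vector<double> stops;
      for (double b : bp) if (b > t + 1e-14 && b < tend - 1e-14) stops.push_back(b);
      std::sort(stops.begin(), stops.end());
      stops.push_back(tend);
      for (double s : stops) {
        dopri5(f, y, 3, t, s, rtol, atol);
        t = s;
      }
    }
    const double t = times[i];
    double theta, omega;
    kin.eval(t, &theta, &omega);
    const double lP = lP_ref - p.r * theta;
    const double vP = -p.r * omega;
    const double a = std::min(std::max(y[0], 0.0), 1.0);

    double l_ce, vtil, v_ce, resid, ftot;
    bool clamped = false;
    if (p.rigid()) {
      const double x = lP - p.ls;
      const double h = p.h();
      l_ce = std::sqrt(std::max(x, 1e-9) * std::max(x, 1e-9) + h * h);
      const double ca = mtu::cos_alpha(l_ce, p);
      v_ce = vP * ca;                 // v_CE_AT = vP exactly
      vtil = v_ce / p.Vmax();
      ftot = p.fo * mtu::ce_force_along(a, l_ce, vtil, p);
      resid = 0.0;
      y[1] = l_ce;
    } else {
      l_ce = y[1];
      vtil = mtu::solve_vtil(a, l_ce, lP, vP, p, &clamped);
      v_ce = vtil * p.Vmax();
      const double ca = mtu::cos_alpha(l_ce, p);
      const double e = (lP - l_ce * ca - p.ls) / p.ls;
      double bT = 0.0;
      if (p.beta_t > 0.0)
        bT = p.beta_t * (p.fo / p.ls) * mtu::dft(e, p.eo) / p.fo;
      const double vT = vP - v_ce / ca;
      ftot = p.fo * (mtu::ft(e, p.eo) + bT * vT);
      resid = mtu::ce_force_along(a, l_ce, vtil, p) -
              (mtu::ft(e, p.eo) + bT * vT);
    }
    const double ca = mtu::cos_alpha(l_ce, p);
    const double x = l_ce * ca;
    const double lT = lP - x;
    const double v_ce_at = p.rigid() ? vP : v_ce / ca;
    const double vT = vP - v_ce_at;

    out(i, 0) = t;
    out(i, 1) = theta;
    out(i, 2) = omega;
    out(i, 3) = f.u_at(t);
    out(i, 4) = a;
    out(i, 5) = l_ce;
    out(i, 6) = std::asin(std::min(p.h() / l_ce, 1.0));
    out(i, 7) = x;
    out(i, 8) = lT;
    out(i, 9) = p.rigid() ? NA_REAL : (lT - p.ls) / p.ls;
    out(i, 10) = v_ce;
    out(i, 11) = v_ce_at;
    out(i, 12) = vT;
    out(i, 13) = ftot;
    out(i, 14) = ftot * p.r;
    out(i, 15) = resid;
    out(i, 16) = y[2];
  }
  colnames(out) = CharacterVector::create(
      "time_s", "theta_rad", "omega_rad_s", "excitation", "activation",
      "l_CE_m", "alpha_rad", "l_CE_AT_m", "l_T_m", "strain", "v_CE_m_s",
      "v_CE_AT_m_s", "v_T_m_s", "F_T_N", "torque_Nm", "resid_norm",
      "W_CE_J");
  return List::create(_["trace"] = out, _["n_clamped"] = (double)f.clamp_count);
}
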