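#pragma once
#include <cmath>
#include <algorithm>
#include <stdexcept>

// Scalar Hill-model characteristic curves and solvers shared by the
// exported Rcpp entry points.  All curves are C1; anchors:
//   fl(1) = 1, support (FL_X0, FL_X3)
//   fv(-1) = 0, fv(0) = 1, fv(+inf) = FV_ECC_MAX
//   fpe(1) = 0, fpe(1 + E0_PE) = 1
//   ft(0) = 0, ft(eo) = 1, quadratic toe to 2/3 eo then linear
namespace mtu {

inline double hermite(double x, double x0, double x1,
                      double p0, double p1, double m0, double m1) {
  const double h = x1 - x0, t = (x - x0) / h, t2 = t * t, t3 = t2 * t;
  return (2 * t3 - 3 * t2 + 1) * p0 + (t3 - 2 * t2 + t) * h * m0 +
         (-2 * t3 + 3 * t2) * p1 + (t3 - t2) * h * m1;
}

inline double dhermite(double x, double x0, double x1,
                       double p0, double p1, double m0, double m1) {
  const double h = x1 - x0, t = (x - x0) / h, t2 = t * t;
  return ((6 * t2 - 6 * t) * p0 + (3 * t2 - 4 * t + 1) * h * m0 +
          (-6 * t2 + 6 * t) * p1 + (3 * t2 - 2 * t) * h * m1) / h;
}

// Active force-length: steep ascending limb, shoulder at the transition
// point, shallow ascending segment to the optimum, descending limb.
constexpr double FL_X0 = 0.4441;   // lower support bound
constexpr double FL_X1 = 0.73;     // ascending-limb transition
constexpr double FL_X2 = 1.0;      // optimal length
constexpr double FL_X3 = 1.8123;   // upper support bound
constexpr double FL_M1 = 0.8616;   // shallow ascending slope at transition
constexpr double FL_Y1 = 1.0 - FL_M1 * (FL_X2 - FL_X1);  // value at transition

inline double fl(double l) {
  if (l <= FL_X0 || l >= FL_X3) return 0.0;
  if (l <= FL_X1) return hermite(l, FL_X0, FL_X1, 0.0, FL_Y1, 0.0, FL_M1);
  if (l <= FL_X2) return hermite(l, FL_X1, FL_X2, FL_Y1, 1.0, FL_M1, 0.0);
  return hermite(l, FL_X2, FL_X3, 1.0, 0.0, 0.0, 0.0);
}

inline double dfl(double l) {
  if (l <= FL_X0 || l >= FL_X3) return 0.0;
  if (l <= FL_X1) return dhermite(l, FL_X0, FL_X1, 0.0, FL_Y1, 0.0, FL_M1);
  if (l <= FL_X2) return dhermite(l, FL_X1, FL_X2, FL_Y1, 1.0, FL_M1, 0.0);
  return dhermite(l, FL_X2, FL_X3, 1.0, 0.0, 0.0, 0.0);
}

// Force-velocity: Hill hyperbola on the concentric branch with curvature
// a/fo = 0.45 (the value that reproduces the corner-blended default
// concentric curve of the reference model: endpoint slopes 5 and 0.25
// with curviness 0.6), saturating exponential on the eccentric branch
// approaching 1.4, C1 at v = 0.
constexpr double FV_ECC_MAX = 1.4;
constexpr double FV_HILL_K = 0.45;          // Hill a/fo curvature
constexpr double FV_SLOPE0 = (1.0 + FV_HILL_K) / FV_HILL_K;  // = 5
constexpr double FV_ECC_RATE = FV_SLOPE0 / (FV_ECC_MAX - 1.0);

inline double fv(double v) {
  if (v <= -1.0) return 0.0;
  if (v <= 0.0) return (1.0 + v) / (1.0 - v / FV_HILL_K);
  return FV_ECC_MAX - (FV_ECC_MAX - 1.0) * std::exp(-FV_ECC_RATE * v);
}

inline double dfv(double v) {
  if (v <= -1.0) return 0.0;
  if (v <= 0.0) {
    const double d = 1.0 - v / FV_HILL_K;
    return FV_SLOPE0 / (d * d);
  }
  return (FV_ECC_MAX - 1.0) * FV_ECC_RATE * std::exp(-FV_ECC_RATE * v);
}

inline double fv_inv(double f) {
  if (f <= 1.0) return (f - 1.0) / (1.0 + f / FV_HILL_K);
  return -std::log((FV_ECC_MAX - f) / (FV_ECC_MAX - 1.0)) / FV_ECC_RATE;
}

// Passive force-length: cubic growth beyond the optimal length,
// reaching 1 at strain E0_PE beyond optimal.
constexpr double E0_PE = 0.7;

inline double fpe(double l) {
  if (l <= 1.0) return 0.0;
  const double s = (l - 1.0) / E0_PE;
  return s * s * s;
}

inline double dfpe(double l) {
  if (l <= 1.0) return 0.0;
  const double s = (l - 1.0) / E0_PE;
  return 3.0 * s * s / E0_PE;
}

// Tendon force-strain: quadratic toe ending at 2/3 of the maximum strain
// eo (normalized force 0.5 there), then linear with slope 1.5/eo so that
// ft(eo) = 1.
inline double toe_end(double eo) { return 2.0 * eo / 3.0; }

inline double ft(double e, double eo) {
  if (e <= 0.0) return 0.0;
  const double et = toe_end(eo);
  if (e <= et) { const double s = e / et; return 0.5 * s * s; }
  return 0.5 + 1.5 * (e - et) / eo;
}

inline double dft(double e, double eo) {
  if (e <= 0.0) return 0.0;
  const double et = toe_end(eo);
  if (e <= et) return e / (et * et);
  return 1.5 / eo;
}

// Normalized strain energy: integral of ft from 0 to e (multiply by
// fo * ls for joules).
inline double ft_energy(double e, double eo) {
  if (e <= 0.0) return 0.0;
  const double et = toe_end(eo);
  if (e <= et) return e * e * e / (6.0 * et * et);
  const double d = e - et;
  return et / 6.0 + 0.5 * d + 0.75 * d * d / eo;
}

// Inverse of ft (force -> strain), used to initialize states from force.
inline double ft_inv(double f, double eo) {
  if (f <= 0.0) return 0.0;
  const double et = toe_end(eo);
  if (f <= 0.5) return et * std::sqrt(2.0 * f);
  return et + (f - 0.5) * eo / 1.5;
}

struct Params {
  double lo;       // optimal CE length, m
  double alpha_o;  // pennation at lo, rad
  double fo;       // maximum isometric CE force, N
  double ls;       // tendon slack length, m
  double vmax;     // maximum shortening velocity, lo/s
  double eo;       // tendon strain at fo (<= 0 encodes the rigid variant)
  double beta;     // dimensionless fiber damping
  double beta_t;   // tendon damping scale (beta_T = beta_t * K_T)
  double r;        // Achilles tendon moment arm, m
  double h() const { return lo * std::sin(alpha_o); }
  double Vmax() const { return lo * vmax; }  // m/s
  bool rigid() const { return eo <= 0.0; }
};

// Pennation geometry from fiber length (constant-thickness model).
inline double cos_alpha(double l_ce, const Params& p) {
  const double h = p.h();
  return std::sqrt(std::max(l_ce * l_ce - h * h, 0.0)) / l_ce;
}

// Normalized CE force along the tendon at given state.
inline double ce_force_along(double a, double l_ce, double vtil, const Params& p) {
  const double lt = l_ce / p.lo;
  return (a * fl(lt) * fv(vtil) + fpe(lt) + p.beta * vtil) * cos_alpha(l_ce, p);
}

// Damped-equilibrium solve for the normalized fiber velocity.
// Equation: Ac*fv(v) + B*v + C0 = 0 with
//   Ac = a*fl*cos(alpha)
//   B  = beta*cos(alpha) + (beta_T*K_T/fo)*Vmax/cos(alpha)
//   C0 = fpe*cos(alpha) - ft - (beta_T*K_T/fo)*vP
// Returns the normalized velocity; *clamped set when the rigid
// below-(-1) branch was taken.
inline double solve_vtil(double a, double l_ce, double lP, double vP,
                         const Params& p, bool* clamped = nullptr) {
  const double ca = cos_alpha(l_ce, p);
  const double lt = l_ce / p.lo;
  const double x = l_ce * ca;                 // CE length along the tendon
  const double lT = lP - x;
  const double e = (lT - p.ls) / p.ls;
  const double ftv = ft(e, p.eo);
  double bT = 0.0;
  if (p.beta_t > 0.0) {
    const double KT = (p.fo / p.ls) * dft(e, p.eo);  // N/m
    bT = p.beta_t * KT / p.fo;                       // 1/(m/s) scale
  }
  const double Ac = a * fl(lt) * ca;
  const double B = p.beta * ca + bT * p.Vmax() / ca;
  const double C0 = fpe(lt) * ca - ftv - bT * vP;
  if (clamped) *clamped = false;

  const double F0 = Ac + C0;             // residual at v = 0
  if (F0 == 0.0) return 0.0;
  if (F0 > 0.0) {                        // concentric: v < 0
    // residual at v = -1 (fv = 0)
    const double Fm1 = C0 - B;
    if (Fm1 >= 0.0) {                    // root at/below -1: fv clamps to 0
      if (clamped) *clamped = true;
      return -C0 / B;                    // linear branch, v <= -1
    }
    // quadratic from (1+v)/(1 - v/k) branch: multiply by (1 - v/k)
    const double k = FV_HILL_K;
    // Ac*(1+v) + (B*v + C0)*(1 - v/k) = 0
    // -> (-B/k) v^2 + (Ac + B - C0/k) v + (Ac + C0) = 0
    const double qa = -B / k;
    const double qb = Ac + B - C0 / k;
    const double qc = Ac + C0;
    const double disc = qb * qb - 4.0 * qa * qc;
    const double sq = std::sqrt(std::max(disc, 0.0));
    // qa < 0; the root in (-1, 0) is (-qb + sq)/(2*qa)
    double v = (-qb + sq) / (2.0 * qa);
    if (v < -1.0) v = -1.0;
    if (v > 0.0) v = 0.0;
    return v;
  }
  // eccentric: v > 0, saturating exponential; Newton with bisection safety
  double lo_b = 0.0, hi_b = 0.1;
  auto Fe = [&](double v) {
    return Ac * (FV_ECC_MAX - (FV_ECC_MAX - 1.0) * std::exp(-FV_ECC_RATE * v)) +
           B * v + C0;
  };
  int guard = 0;
  while (Fe(hi_b) < 0.0 && guard++ < 200) hi_b *= 2.0;
  double v = 0.5 * (lo_b + hi_b);
  for (int it = 0; it < 100; ++it) {
    const double f = Fe(v);
    if (f > 0.0) hi_b = v; else lo_b = v;
    const double df = Ac * (FV_ECC_MAX - 1.0) * FV_ECC_RATE *
                      std::exp(-FV_ECC_RATE * v) + B;
    double vn = v - f / df;
    if (!(vn > lo_b && vn < hi_b)) vn = 0.5 * (lo_b + hi_b);
    if (std::fabs(vn - v) < 1e-14) { v = vn; break; }
    v = vn;
  }
  return v;
}

// Static (v = 0) equilibrium: fiber length solving
//   ft(strain) = (a*fl + fpe)*cos(alpha)
// parameterized by the along-tendon CE length x.  Returns fiber length.
inline double static_fiber_length(double a, double lP, const Params& p) {
  const double h = p.h();
  auto resid = [&](double x) {
    const double l_ce = std::sqrt(x * x + h * h);
    const double ca = x / l_ce;
    const double lt = l_ce / p.lo;
    const double e = (lP - x - p.ls) / p.ls;
    return ft(e, p.eo) - (a * fl(lt) + fpe(lt)) * ca;
  };
  const double x_hi = std::min(lP - 0.25 * p.ls, 2.4 * p.lo);
  const double x_lo = 1e-9;
  // residual is positive near x_lo (stretched tendon, pennate CE transmits
  // nothing) and non-positive once the tendon goes slack: scan + bisect
  const int n = 256;
  double a0 = x_lo, f0 = resid(a0), b0 = a0;
  bool found = false;
  for (int i = 1; i <= n; ++i) {
    const double x = x_lo + (x_hi - x_lo) * i / n;
    const double f = resid(x);
    if ((f0 > 0.0 && f <= 0.0) || (f0 < 0.0 && f >= 0.0)) {
      b0 = x; found = true; break;
    }
    a0 = x; f0 = f;
  }
  if (!found) {
    // degenerate: no tension anywhere -- put the tendon exactly at slack
    double x = lP - p.ls;
    if (x < x_lo) x = x_lo;
    return std::sqrt(x * x + h * h);
  }
  double lo_b = a0, hi_b = b0;
  for (int it = 0; it < 200; ++it) {
    const double m = 0.5 * (lo_b + hi_b);
    const double fm = resid(m);
    if ((fm > 0.0) == (f0 > 0.0)) lo_b = m; else hi_b = m;
    if (hi_b - lo_b < 1e-15) break;
  }
  const double x = 0.5 * (lo_b + hi_b);
  return std::sqrt(x * x + h * h);
}

// Static tendon force at equilibrium (N).
inline double static_force(double a, double lP, const Params& p) {
  if (p.rigid()) {
    double x = lP - p.ls;
    const double h = p.h();
    if (x <= 0.0) return 0.0;
    const double l_ce = std::sqrt(x * x + h * h);
    const double lt = l_ce / p.lo;
    return p.fo * (a * fl(lt) + fpe(lt)) * (x / l_ce);
  }
  const double l_ce = static_fiber_length(a, lP, p);
  const double e = (lP - l_ce * cos_alpha(l_ce, p) - p.ls) / p.ls;
  return p.fo * ft(e, p.eo);
}

}  // namespace mtu
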