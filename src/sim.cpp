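// Forward model of the cGMP -> (CNGC-DF, PKG-DF) -> (ClC, NaC) cascade.
//
// State is the pair of downstream factors (Z, W); the stimulus S(t), the
// Hill activations X, Y and the channel activities are algebraic.  The
// integrator is an adaptive Cash-Karp RK45 with dense sampling on an
// arbitrary output grid (typically the 1 s recording grid).  Everything is
// deterministic; all randomness lives on the R side.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hill activation S^n / (K^n + S^n), computed in log space so that extreme
// K/S ratios (the priors allow K -> 0) neither overflow nor underflow.
static inline double hill(double S, double K, double n) {
  if (S <= 0.0) return 0.0;
  if (K <= 0.0) return 1.0;
  double r = n * (std::log(K) - std::log(S));
  if (r > 700.0) return 0.0;
  return 1.0 / (1.0 + std::exp(r));
}

// Pathway modifier m(U; sign, g): NONE -> 1, ACTIVATION -> 1 + gU,
// INHIBITION -> 1 / (1 + gU).  Equals 1 whenever g = 0 (model nesting).
static inline double modif(double U, int sign, double g) {
  if (sign == 1) return 1.0 + g * U;
  if (sign == 2) return 1.0 / (1.0 + g * U);
  return 1.0;
}

static inline double sat(double u) { return u / (1.0 + u); }

struct Pars {
  double KX, nX, KY, nY, kZ, kW;
  double gZW, gWCl, gZNa, gWZ;   // gains for Z->W, W->Cl, Z->Na, W->Z
  int sZW, sWCl, sZNa, sWZ;      // signs (0 none, 1 activation, 2 inhibition)
  double AZ, AW;                 // per-cell downstream gains
  double Seff, tauS;             // asymptotic stimulus (bath-corrected), rise tau
  double pkg;                    // 0 when PKG is inhibited (KT5823)
};

static inline double stim(double t, const Pars &p) {
  return p.Seff * (1.0 - std::exp(-t / p.tauS));
}

static inline void deriv(double t, double Z, double W, const Pars &p,
                         double &dZ, double &dW) {
  double S = stim(t, p);
  double X = hill(S, p.KX, p.nX);
  double Y = p.pkg * hill(S, p.KY, p.nY);
  dZ = p.kZ * (p.AZ * X * modif(W, p.sWZ, p.gWZ) - Z);
  dW = p.kW * (p.AW * Y * modif(Z, p.sZW, p.gZW) - W);
}

// Cash-Karp embedded RK45 step; returns the scaled error estimate.
static inline double ck_step(double t, double h, double Z, double W,
                             const Pars &p, double atol, double rtol,
                             double &Z5, double &W5) {
  static const double
    b21 = 1.0 / 5.0,
    b31 = 3.0 / 40.0, b32 = 9.0 / 40.0,
    b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0,
    b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0,
    b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
    b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0,
    c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
    c6 = 512.0 / 1771.0,
    d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
    d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
    d6 = c6 - 1.0 / 4.0;

  double k1z, k1w, k2z, k2w, k3z, k3w, k4z, k4w, k5z, k5w, k6z, k6w;
  deriv(t, Z, W, p, k1z, k1w);
  deriv(t + h / 5.0, Z + h * b21 * k1z, W + h * b21 * k1w, p, k2z, k2w);
  deriv(t + 3.0 * h / 10.0, Z + h * (b31 * k1z + b32 * k2z),
        W + h * (b31 * k1w + b32 * k2w), p, k3z, k3w);
  deriv(t + 3.0 * h / 5.0, Z + h * (b41 * k1z + b42 * k2z + b43 * k3z),
        W + h * (b41 * k1w + b42 * k2w + b43 * k3w), p, k4z, k4w);
  deriv(t + h, Z + h * (b51 * k1z + b52 * k2z + b53 * k3z + b54 * k4z),
        W + h * (b51 * k1w + b52 * k2w + b53 * k3w + b54 * k4w), p, k5z, k5w);
  deriv(t + 7.0 * h / 8.0,
        Z + h * (b61 * k1z + b62 * k2z + b63 * k3z + b64 * k4z + b65 * k5z),
        W + h * (b61 * k1w + b62 * k2w + b63 * k3w + b64 * k4w + b65 * k5w),
        p, k6z, k6w);

  Z5 = Z + h * (c1 * k1z + c3 * k3z + c4 * k4z + c6 * k6z);
  W5 = W + h * (c1 * k1w + c3 * k3w + c4 * k4w + c6 * k6w);
  double errZ = h * (d1 * k1z + d3 * k3z + d4 * k4z + d5 * k5z + d6 * k6z);
  double errW = h * (d1 * k1w + d3 * k3w + d4 * k4w + d5 * k5w + d6 * k6w);
  double sZ = atol + rtol * std::max(std::fabs(Z), std::fabs(Z5));
  double sW = atol + rtol * std::max(std::fabs(W), std::fabs(W5));
  double e = std::max(std::fabs(errZ) / sZ, std::fabs(errW) / sW);
  return e;
}

// Integrate (Z, W) from t0 to t1 in place.  Throws on step-size underflow.
static void advance(double &t, double t1, double &Z, double &W, double &h,
                    const Pars &p, double atol, double rtol) {
  const double hmin = 1e-10;
  long nstep = 0;
  while (t < t1) {
    if (h > t1 - t) h = t1 - t;
    double Z5, W5;
    double err = ck_step(t, h, Z, W, p, atol, rtol, Z5, W5);
    if (err <= 1.0 || h <= hmin * 1.0001) {
      t += h;
      Z = Z5 > 0.0 ? Z5 : 0.0;     // dynamics are nonnegative by construction
      W = W5 > 0.0 ? W5 : 0.0;
      if (Z > 1e9) Z = 1e9;        // cap runaway mutual activation; channel
      if (W > 1e9) W = 1e9;        // activities are saturated long before this
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(err, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    }
    if (h < hmin) h = hmin;
    if (++nstep > 50000000L)
      stop("numerical-failure: step-size underflow in RK45 (t = %f)", t);
  }
}

static Pars unpack(const IntegerVector &signs, const NumericVector &th,
                   const NumericVector &ph, const NumericVector &cond) {
  Pars p;
  p.sZW = signs[0]; p.sWCl = signs[1]; p.sZNa = signs[2]; p.sWZ = signs[3];
  p.KX = th[0]; p.nX = th[1]; p.KY = th[2]; p.nY = th[3];
  p.kZ = th[4]; p.kW = th[5];
  p.gZW = th[6]; p.gWCl = th[7]; p.gZNa = th[8]; p.gWZ = th[9];
  p.AZ = ph[4]; p.AW = ph[5];
  p.tauS = ph[1];
  p.Seff = cond[2];
  p.pkg = cond[3];
  return p;
}

// th:   KX nX KY nY kZ kW gZW gWCl gZNa gWZ
// ph:   VK tauS ACl ANa AZ AW
// cond: etaCl etaNa Seff pkg
// [[Rcpp::export(name = ".sim_core_cpp")]]
NumericMatrix sim_core_cpp(NumericVector times, IntegerVector signs,
                           NumericVector th, NumericVector ph,
                           NumericVector cond,
                           double rtol = 1e-6, double atol = 1e-8,
                           bool full = false) {
  const int n = times.size();
  if (n < 1) stop("invalid-argument: empty output grid");
  Pars p = unpack(signs, th, ph, cond);
  if (p.tauS <= 0.0) stop("invalid-argument: tau_S must be positive");
  const double VK = ph[0], ACl = ph[2], ANa = ph[3];
  const double etaCl = cond[0], etaNa = cond[1];

  NumericMatrix out(n, full ? 9 : 1);
  double t = 0.0, Z = 0.0, W = 0.0, h = 0.1;
  for (int i = 0; i < n; ++i) {
    double ti = times[i];
    if (ti < t) stop("invalid-argument: output times must be nondecreasing");
    if (ti > t) advance(t, ti, Z, W, h, p, atol, rtol);
    double cl = sat(Z * modif(W, p.sWCl, p.gWCl));
    double na = sat(W * modif(Z, p.sZNa, p.gZNa));
    double V = VK - etaCl * ACl * cl + etaNa * ANa * na;
    if (full) {
      double S = stim(ti, p);
      out(i, 0) = ti; out(i, 1) = V; out(i, 2) = S;
      out(i, 3) = hill(S, p.KX, p.nX);
      out(i, 4) = p.pkg * hill(S, p.KY, p.nY);
      out(i, 5) = Z; out(i, 6) = W; out(i, 7) = cl; out(i, 8) = na;
    } else {
      out(i, 0) = V;
    }
  }
  return out;
}

// Gaussian log likelihood of one series against a model trace:
// -T log(sqrt(2 pi) sigma) - sum(dV^2) / (2 sigma^2).
// [[Rcpp::export(name = ".loglik_series_cpp")]]
double loglik_series_cpp(NumericVector v, NumericVector vhat, double sigma) {
  const int n = v.size();
  if (vhat.size() != n) stop("invalid-input: length mismatch");
  if (sigma <= 0.0) stop("invalid-input: sigma must be positive");
  double ss = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = v[i] - vhat[i];
    ss += d * d;
  }
  return -n * std::log(std::sqrt(2.0 * M_PI) * sigma) -
         ss / (2.0 * sigma * sigma);
}
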