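#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of a periodic table sampled on a uniform grid over
// [0, 2*pi); theta may be any real value.
static inline double interp_periodic(const std::vector<double>& tab, double theta) {
  const int n = (int) tab.size();
  double u = theta * n / (2.0 * M_PI);
  u -= std::floor(u / n) * n;           // into [0, n)
  int j = (int) u;
  double f = u - j;
  int j1 = (j + 1 == n) ? 0 : j + 1;
  return tab[j] * (1.0 - f) + tab[j1] * f;
}

// Euler-Maruyama integration of the phase-reduced pair driven by a
// partially correlated OU pair:
//   theta1' = 1 + eps * D1(theta1) x,   theta2' = 1 + eps * D2(theta2) y + eps^2 w
//   x' = -x/tau + xi_x/tau,             y' = -y/tau + xi_y/tau
// PRCs are passed as lookup tables on a uniform [0, 2*pi) grid. Phases are
// returned unwrapped, thinned to every `record_every` steps after
// `burn_steps`. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_phase_pair(NumericVector prc1, NumericVector prc2,
                    double eps, double omega, double tau, double c,
                    double dt, int nsteps, int burn_steps, int record_every) {
  std::vector<double> d1 = as<std::vector<double>>(prc1);
  std::vector<double> d2 = as<std::vector<double>>(prc2);
  const double sq = std::sqrt(dt) / tau;
  const double rc = std::sqrt(c), rp = std::sqrt(1.0 - c);
  const double sig0 = std::sqrt(1.0 / (2.0 * tau));
  // the drive is the variance-normalized process sqrt(tau)*x (variance 1/2
  // for every tau), so the correlated-input power does not depend on tau
  const double st = std::sqrt(tau);

  RNGScope scope;
  double s0c = R::norm_rand(), s0x = R::norm_rand(), s0y = R::norm_rand();
  double x = sig0 * (rc * s0c + rp * s0x);
  double y = sig0 * (rc * s0c + rp * s0y);
  double th1 = 0.0, th2 = 0.0;

  int nrec = 0;
  for (int i = burn_steps; i < nsteps; i += record_every) nrec++;
  NumericVector out1(nrec), out2(nrec);

  int k = 0;
  for (int i = 0; i < nsteps; ++i) {
    if (i >= burn_steps && ((i - burn_steps) % record_every) == 0) {
      out1[k] = th1; out2[k] = th2; ++k;
    }
    double f1 = 1.0 + eps * interp_periodic(d1, th1) * st * x;
    double f2 = 1.0 + eps * interp_periodic(d2, th2) * st * y + eps * eps * omega;
    th1 += dt * f1;
    th2 += dt * f2;
    double zc = R::norm_rand(), zx = R::norm_rand(), zy = R::norm_rand();
    x += -x * dt / tau + sq * (rc * zc + rp * zx);
    y += -y * dt / tau + sq * (rc * zc + rp * zy);
    if (!R_finite(th1) || !R_finite(th2) || !R_finite(x) || !R_finite(y))
      stop("phase-pair integration blew up at step %d", i);
  }
  return List::create(_["theta1"] = out1, _["theta2"] = out2);
}

struct MLPar {
  double VK, VL, VCa, gK, gL, gCa, C, Va, Vb, Vc, Vd, I, phi;
};

static inline MLPar as_mlpar(const NumericVector& p) {
  MLPar q;
  q.VK = p["VK"]; q.VL = p["VL"]; q.VCa = p["VCa"];
  q.gK = p["gK"]; q.gL = p["gL"]; q.gCa = p["gCa"]; q.C = p["C"];
  q.Va = p["Va"]; q.Vb = p["Vb"]; q.Vc = p["Vc"]; q.Vd = p["Vd"];
  q.I = p["I"]; q.phi = p["phi"];
  return q;
}

static inline void ml_rhs(const MLPar& p, double V, double w, double Iext,
                          double& dV, double& dw) {
  double minf = 0.5 * (1.0 + std::tanh((V - p.Va) / p.Vb));
  double winf = 0.5 * (1.0 + std::tanh((V - p.Vc) / p.Vd));
  double tw   = 1.0 / std::cosh((V - p.Vc) / (2.0 * p.Vd));
  dV = (p.I + Iext - p.gL * (V - p.VL) - p.gK * w * (V - p.VK)
        - p.gCa * minf * (V - p.VCa)) / p.C;
  dw = p.phi * (winf - w) / tw;
}

// Deterministic Morris-Lecar, fixed-step RK4; records every `record_every`
// steps. Used for limit-cycle detection and dense cycle resampling.
// [[Rcpp::export]]
NumericMatrix cpp_ml_det(NumericVector params, NumericVector state0,
                         double dt, int nsteps, int record_every) {
  MLPar p = as_mlpar(params);
  double V = state0[0], w = state0[1];
  int nrec = nsteps / record_every + 1;
  NumericMatrix out(nrec, 3);
  int k = 0;
  for (int i = 0; i <= nsteps; ++i) {
    if (i % record_every == 0 && k < nrec) {
      out(k, 0) = i * dt; out(k, 1) = V; out(k, 2) = w; ++k;
    }
    double k1V, k1w, k2V, k2w, k3V, k3w, k4V, k4w;
    ml_rhs(p, V, w, 0.0, k1V, k1w);
    ml_rhs(p, V + 0.5 * dt * k1V, w + 0.5 * dt * k1w, 0.0, k2V, k2w);
    ml_rhs(p, V + 0.5 * dt * k2V, w + 0.5 * dt * k2w, 0.0, k3V, k3w);
    ml_rhs(p, V + dt * k3V, w + dt * k3w, 0.0, k4V, k4w);
    V += dt / 6.0 * (k1V + 2 * k2V + 2 * k3V + k4V);
    w += dt / 6.0 * (k1w + 2 * k2w + 2 * k3w + k4w);
    if (!R_finite(V) || !R_finite(w))
      stop("deterministic ML integration blew up at step %d", i);
  }
  return out;
}

// Euler-Maruyama integration of two Morris-Lecar cells driven by a
// partially correlated OU pair; cell 1 receives sigma*x, cell 2 sigma*y.
// Returns t, V1, w1, V2, w2, x, y thinned to every `record_every` steps.
// [[Rcpp::export]]
NumericMatrix cpp_ml_pair(NumericVector params1, NumericVector params2,
                          double sigma, double tau, double c,
                          double dt, int nsteps, int record_every,
                          NumericVector state0) {
  MLPar p1 = as_mlpar(params1), p2 = as_mlpar(params2);
  const double sq = std::sqrt(dt) / tau;
  const double rc = std::sqrt(c), rp = std::sqrt(1.0 - c);
  const double sig0 = std::sqrt(1.0 / (2.0 * tau));
  const double st = std::sqrt(tau); // variance-normalized drive, as above

  RNGScope scope;
  double s0c = R::norm_rand(), s0x = R::norm_rand(), s0y = R::norm_rand();
  double x = sig0 * (rc * s0c + rp * s0x);
  double y = sig0 * (rc * s0c + rp * s0y);
  double V1 = state0[0], w1 = state0[1], V2 = state0[2], w2 = state0[3];

  int nrec = nsteps / record_every + 1;
  NumericMatrix out(nrec, 7);
  int k = 0;
  for (int i = 0; i <= nsteps; ++i) {
    if (i % record_every == 0 && k < nrec) {
      out(k, 0) = i * dt; out(k, 1) = V1; out(k, 2) = w1;
      out(k, 3) = V2; out(k, 4) = w2; out(k, 5) = x; out(k, 6) = y; ++k;
    }
    double dV1, dw1, dV2, dw2;
    ml_rhs(p1, V1, w1, sigma * st * x, dV1, dw1);
    ml_rhs(p2, V2, w2, sigma * st * y, dV2, dw2);
    V1 += dt * dV1; w1 += dt * dw1;
    V2 += dt * dV2; w2 += dt * dw2;
    double zc = R::norm_rand(), zx = R::norm_rand(), zy = R::norm_rand();
    x += -x * dt / tau + sq * (rc * zc + rp * zx);
    y += -y * dt / tau + sq * (rc * zc + rp * zy);
    if (!R_finite(V1) || !R_finite(V2))
      stop("stochastic ML integration blew up at step %d", i);
  }
  return out;
}
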