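#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bernoulli function B(z) = z / (exp(z) - 1), stable near 0.
static inline double bern(double z) {
  if (std::fabs(z) < 1e-8) return 1.0 - 0.5 * z;
  if (z > 700.0) return 0.0;                  // exp overflow guard
  if (z < -700.0) return -z;
  return z / (std::expm1(z));
}

// Conservative drift-diffusion step matrix (Scharfetter-Gummel /
// exponential-fitting flux) with no-flux boundaries:
//   dP_i/dt = (J_{i-1/2} - J_{i+1/2}) / dx,
//   J_{i+1/2} = (D/dx) * ( B(-w_i) P_i - B(w_i) P_{i+1} ),
//   w_i = -(U_{i+1} - U_i) / D.
// The discrete stationary solution is exactly P_i ~ exp(-U_i / D).
// Crank-Nicolson stepping with a few backward-Euler (Rannacher) start
// steps; the tridiagonal solve is the Thomas algorithm.
//
// flip_drift = true implements the drift sign of the printed transport
// form (archaeology only); false is the Langevin-consistent equation.
// [[Rcpp::export]]
NumericMatrix fp_solve_cpp(NumericVector U, double D, double dx,
                           NumericVector p0, double dt, int n_steps,
                           IntegerVector save_steps, bool flip_drift,
                           int n_rannacher) {
  const int n = U.size();
  const int n_save = save_steps.size();
  NumericMatrix out(n, n_save);

  // interface Bernoulli weights (constant in time)
  std::vector<double> bm(n - 1), bp(n - 1); // B(-w), B(w) at i+1/2
  const double r = D / (dx * dx);
  for (int i = 0; i < n - 1; ++i) {
    double w = -(U[i + 1] - U[i]) / D;
    if (flip_drift) w = -w;
    bm[i] = bern(-w);
    bp[i] = bern(w);
  }
  // generator A (tridiagonal): dP/dt = A P
  std::vector<double> lo(n), di(n), up(n); // A sub/diag/super
  for (int i = 0; i < n; ++i) {
    double a = 0.0, b = 0.0, c = 0.0;
    if (i > 0) { a = r * bm[i - 1]; b -= r * bp[i - 1]; }
    if (i < n - 1) { c = r * bp[i]; b -= r * bm[i]; }
    lo[i] = a; di[i] = b; up[i] = c;
  }

  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> rhs(n), cw(n), dw(n);
  int save_pos = 0;
  // allow saving the initial condition (save step 0)
  while (save_pos < n_save && save_steps[save_pos] == 0) {
    for (int i = 0; i < n; ++i) out(i, save_pos) = p[i];
    ++save_pos;
  }

  for (int s = 1; s <= n_steps && save_pos < n_save; ++s) {
    const double th = (s <= n_rannacher) ? 1.0 : 0.5; // BE start, then CN
    // rhs = (I + (1-th) dt A) p
    for (int i = 0; i < n; ++i) {
      double v = p[i];
      if (th < 1.0) {
        double ap = di[i] * p[i];
        if (i > 0) ap += lo[i] * p[i - 1];
        if (i < n - 1) ap += up[i] * p[i + 1];
        v += (1.0 - th) * dt * ap;
      }
      rhs[i] = v;
    }
    // solve (I - th dt A) p_new = rhs  (Thomas)
    const double f = th * dt;
    double b0 = 1.0 - f * di[0];
    cw[0] = (-f * up[0]) / b0;
    dw[0] = rhs[0] / b0;
    for (int i = 1; i < n; ++i) {
      double ai = -f * lo[i];
      double bi = 1.0 - f * di[i];
      double ci = -f * up[i];
      double m = bi - ai * cw[i - 1];
      cw[i] = ci / m;
      dw[i] = (rhs[i] - ai * dw[i - 1]) / m;
    }
    p[n - 1] = dw[n - 1];
    for (int i = n - 2; i >= 0; --i) p[i] = dw[i] - cw[i] * p[i + 1];
    // CN can undershoot marginally; clip tiny negatives, preserving mass
    double neg = 0.0;
    for (int i = 0; i < n; ++i) if (p[i] < 0) { neg += p[i]; p[i] = 0.0; }
    if (neg != 0.0) {
      double tot = 0.0;
      for (int i = 0; i < n; ++i) tot += p[i];
      if (tot > 0) { double sc = (tot + neg) / tot; for (int i = 0; i < n; ++i) p[i] *= sc; }
    }
    while (save_pos < n_save && save_steps[save_pos] == s) {
      for (int i = 0; i < n; ++i) out(i, save_pos) = p[i];
      ++save_pos;
    }
  }
  return out;
}
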