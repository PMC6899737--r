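#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Prey-depletion right-hand side:
//   dN/dt = -pred * c * N^h / (1 + c * b * N^h) - m * N
// with c, b already evaluated at the trial temperature.
static inline double rhs(double N, double c, double b, double h,
                         double m, bool pred) {
  if (N <= 0.0) return 0.0;
  double Nh = (h == 1.0) ? N : std::pow(N, h);
  double feed = pred ? c * Nh / (1.0 + c * b * Nh) : 0.0;
  return -feed - m * N;
}

// Adaptive Cash-Karp RK4(5) for the scalar depletion ODE.  Error control is
// err = |delta| / (atol + rtol * |y|); steps shrink by 0.9 * err^-0.25 on
// rejection and grow by at most 5x on acceptance.
static double integrate_one(double N0, double c, double b, double h,
                            double m, double t_end,
                            double rtol, double atol) {
  if (N0 <= 0.0 || t_end <= 0.0) return N0 > 0.0 ? N0 : 0.0;

  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                      b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double d1 = c1 - 2825.0 / 27648.0,
                      d3 = c3 - 18575.0 / 48384.0,
                      d4 = c4 - 13525.0 / 55296.0,
                      d5 = -277.0 / 14336.0,
                      d6 = c6 - 1.0 / 4.0;

  const bool pred = (c > 0.0);
  double t = 0.0, y = N0;
  double dt = t_end;
  const int max_steps = 100000;

  for (int step = 0; step < max_steps && t < t_end; ++step) {
    if (t + dt > t_end) dt = t_end - t;

    double k1 = rhs(y, c, b, h, m, pred);
    double k2 = rhs(y + dt * b21 * k1, c, b, h, m, pred);
    double k3 = rhs(y + dt * (b31 * k1 + b32 * k2), c, b, h, m, pred);
    double k4 = rhs(y + dt * (b41 * k1 + b42 * k2 + b43 * k3),
                    c, b, h, m, pred);
    double k5 = rhs(y + dt * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4),
                    c, b, h, m, pred);
    double k6 = rhs(y + dt * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 +
                              b65 * k5),
                    c, b, h, m, pred);

    double ynew = y + dt * (c1 * k1 + c3 * k3 + c4 * k4 + c6 * k6);
    double delta = dt * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 + d6 * k6);
    double scale = atol + rtol * std::max(std::fabs(y), std::fabs(ynew));
    double err = std::fabs(delta) / scale;

    if (!std::isfinite(err)) {
      dt *= 0.1;
      if (dt < 1e-14 * t_end)
        stop("depletion solver failed: step size underflow");
      continue;
    }
    if (err > 1.0) {
      dt *= std::max(0.2, 0.9 * std::pow(err, -0.25));
      if (dt < 1e-14 * t_end)
        stop("depletion solver failed: step size underflow");
      continue;
    }
    t += dt;
    y = ynew;
    double grow = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 5.0;
    dt *= std::min(5.0, grow);
  }
  if (t < t_end) stop("depletion solver failed: max step count exceeded");
  return y;
}

// [[Rcpp::export(name = ".cpp_depletion_endpoint")]]
NumericVector cpp_depletion_endpoint(NumericVector N0, NumericVector c,
                                     NumericVector b, double h,
                                     NumericVector m, NumericVector t_end,
                                     double rtol, double atol) {
  int n = N0.size();
  if (c.size() != n || b.size() != n || m.size() != n || t_end.size() != n)
    stop("all parameter vectors must have the same length");
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = integrate_one(N0[i], c[i], b[i], h, m[i], t_end[i], rtol, atol);
  return out;
}
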