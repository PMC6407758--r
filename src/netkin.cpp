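// Mass-action kernels shared by the native integrator and the RK4 oracle.
//
// A kinetic scheme is flattened into a term table: term t contributes
//   w[t] * prod_j x[j]^E(t,j)
// to component target[t] of dx/dt, where w folds sign, stoichiometric
// multiplier and rate-constant value. R_pow() is used so integer exponents
// of negative states (generic ODE usage, e.g. the damped oscillator) are
// well defined.

#include <Rcpp.h>
using namespace Rcpp;

static inline double term_prod(const NumericMatrix& E, int t, const double* x, int n) {
  double p = 1.0;
  for (int j = 0; j < n; ++j) {
    double e = E(t, j);
    if (e != 0.0) p *= R_pow(x[j], e);
  }
  return p;
}

static void rhs_fill(const double* x, double* dx, const NumericVector& w,
                     const IntegerVector& target, const NumericMatrix& E, int n) {
  int m = w.size();
  for (int i = 0; i < n; ++i) dx[i] = 0.0;
  for (int t = 0; t < m; ++t)
    dx[target[t]] += w[t] * term_prod(E, t, x, n);
}

// [[Rcpp::export]]
NumericVector nk_rhs(NumericVector x, NumericVector w, IntegerVector target,
                     NumericMatrix E) {
  int n = x.size();
  NumericVector dx(n);
  rhs_fill(REAL(x), REAL(dx), w, target, E, n);
  return dx;
}

// [[Rcpp::export]]
NumericMatrix nk_jac(NumericVector x, NumericVector w, IntegerVector target,
                     NumericMatrix E) {
  int n = x.size(), m = w.size();
  NumericMatrix J(n, n);
  for (int t = 0; t < m; ++t) {
    int i = target[t];
    for (int j = 0; j < n; ++j) {
      double e = E(t, j);
      if (e == 0.0) continue;
      double d = e * R_pow(x[j], e - 1.0);  // R_pow(0,0) = 1 handles e = 1 at x = 0
      if (d == 0.0) continue;
      for (int l = 0; l < n; ++l) {
        if (l == j) continue;
        double el = E(t, l);
        if (el != 0.0) d *= R_pow(x[l], el);
      }
      J(i, j) += w[t] * d;
    }
  }
  return J;
}

// Classical fixed-step RK4; records every (n_steps / n_print)-th state.
// n_steps must be a multiple of n_print (enforced on the R side).
// [[Rcpp::export]]
NumericMatrix nk_rk4(NumericVector x0, double t0, double t1, int n_steps,
                     int n_print, NumericVector w, IntegerVector target,
                     NumericMatrix E) {
  int n = x0.size();
  double h = (t1 - t0) / n_steps;
  int every = n_steps / n_print;
  NumericMatrix out(n_print + 1, n);
  std::vector<double> x(n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int i = 0; i < n; ++i) { x[i] = x0[i]; out(0, i) = x0[i]; }
  int row = 1;
  for (int s = 0; s < n_steps; ++s) {
    rhs_fill(x.data(), k1.data(), w, target, E, n);
    for (int i = 0; i < n; ++i) tmp[i] = x[i] + 0.5 * h * k1[i];
    rhs_fill(tmp.data(), k2.data(), w, target, E, n);
    for (int i = 0; i < n; ++i) tmp[i] = x[i] + 0.5 * h * k2[i];
    rhs_fill(tmp.data(), k3.data(), w, target, E, n);
    for (int i = 0; i < n; ++i) tmp[i] = x[i] + h * k3[i];
    rhs_fill(tmp.data(), k4.data(), w, target, E, n);
    for (int i = 0; i < n; ++i)
      x[i] += (h / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if ((s + 1) % every == 0) {
      for (int i = 0; i < n; ++i) out(row, i) = x[i];
      ++row;
    }
  }
  return out;
}
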