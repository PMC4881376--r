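#include <Rcpp.h>
using namespace Rcpp;

// Fuzzy c-means (Bezdek) alternating optimization from a given initial
// membership matrix. Returns converged memberships, centers, and the
// per-iteration objective trace J = sum_i sum_j u_ij^m ||x_i - c_j||^2.
//
// Convergence: max |u_new - u_old| < tol. A point coincident with a center
// receives full membership in (the lowest-indexed) coincident center.
// [[Rcpp::export(name = ".fcm_core")]]
List fcm_core(NumericMatrix X, NumericMatrix U0, double m,
              double tol, int max_iter) {
  const int n = X.nrow(), d = X.ncol(), k = U0.ncol();
  NumericMatrix U(clone(U0));
  NumericMatrix C(k, d);
  NumericMatrix D2(n, k);
  std::vector<double> trace;
  trace.reserve(64);
  int iter = 0;
  bool converged = false;
  const bool m2 = (m == 2.0);   // fast path: u^2 and exponent 1

  while (iter < max_iter) {
    ++iter;
    // center update: c_j = sum_i u_ij^m x_i / sum_i u_ij^m
    std::vector<double> wsum(k, 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < k; ++j) {
        double u = U(i, j);
        double w = m2 ? u * u : std::pow(u, m);
        wsum[j] += w;
        for (int c = 0; c < d; ++c) C(j, c) += w * X(i, c);
      }
    for (int j = 0; j < k; ++j) {
      double w = wsum[j] > 0 ? wsum[j] : 1.0;
      for (int c = 0; c < d; ++c) C(j, c) /= w;
    }
    // squared distances
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int c = 0; c < d; ++c) {
          double t = X(i, c) - C(j, c);
          s += t * t;
        }
        D2(i, j) = s;
      }
    // membership update + objective (J uses the *current* centers and the
    // memberships that generated them, evaluated before the update)
    double J = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < k; ++j) {
        double u = U(i, j);
        J += (m2 ? u * u : std::pow(u, m)) * D2(i, j);
      }
    trace.push_back(J);

    double maxdelta = 0.0;
    const double expo = 1.0 / (m - 1.0);
    std::vector<double> inv(k);
    for (int i = 0; i < n; ++i) {
      int zero = -1;
      for (int j = 0; j < k; ++j)
        if (D2(i, j) <= 0.0) { zero = j; break; }
      if (zero >= 0) {
        for (int j = 0; j < k; ++j) {
          double u = (j == zero) ? 1.0 : 0.0;
          maxdelta = std::max(maxdelta, std::fabs(u - U(i, j)));
          U(i, j) = u;
        }
      } else if (m2) {
        // m = 2: u_ij = (1/d2_ij) / sum_l (1/d2_il)
        double s = 0.0;
        for (int j = 0; j < k; ++j) { inv[j] = 1.0 / D2(i, j); s += inv[j]; }
        for (int j = 0; j < k; ++j) {
          double u = inv[j] / s;
          maxdelta = std::max(maxdelta, std::fabs(u - U(i, j)));
          U(i, j) = u;
        }
      } else {
        // u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1)) with d^2 precomputed
        for (int j = 0; j < k; ++j) {
          double s = 0.0;
          for (int l = 0; l < k; ++l)
            s += std::pow(D2(i, j) / D2(i, l), expo);
          double u = 1.0 / s;
          maxdelta = std::max(maxdelta, std::fabs(u - U(i, j)));
          U(i, j) = u;
        }
      }
    }
    if (maxdelta < tol) { converged = true; break; }
  }

  // final centers/objective for the converged memberships
  std::vector<double> wsum(k, 0.0);
  std::fill(C.begin(), C.end(), 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) {
      double u = U(i, j);
      double w = m2 ? u * u : std::pow(u, m);
      wsum[j] += w;
      for (int c = 0; c < d; ++c) C(j, c) += w * X(i, c);
    }
  for (int j = 0; j < k; ++j) {
    double w = wsum[j] > 0 ? wsum[j] : 1.0;
    for (int c = 0; c < d; ++c) C(j, c) /= w;
  }
  double J = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = X(i, c) - C(j, c);
        s += t * t;
      }
      double u = U(i, j);
      J += (m2 ? u * u : std::pow(u, m)) * s;
    }
  trace.push_back(J);

  return List::create(_["membership"] = U, _["centers"] = C,
                      _["objective"] = J,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = iter, _["converged"] = converged);
}
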