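#include <Rcpp.h>
using namespace Rcpp;

// Nonlinear least squares for y ~ a * exp(-((t - b)/c)^2) by
// Levenberg-Marquardt on the 3x3 normal equations, with moment-based
// initialization. Returns c(a, b, c, sse, converged_flag).
//
// The model has no baseline term; the initializer subtracts min(y) only to
// weight the moments, not in the fit itself.

static double model_sse(const NumericVector& t, const NumericVector& y,
                        double a, double b, double c) {
  double sse = 0.0;
  for (int i = 0; i < t.size(); ++i) {
    double z = (t[i] - b) / c;
    double r = y[i] - a * std::exp(-z * z);
    sse += r * r;
  }
  return sse;
}

// [[Rcpp::export(name = ".fit_gaussian_cpp")]]
NumericVector fit_gaussian_cpp(NumericVector t, NumericVector y,
                               int max_iter = 200, double tol = 1e-12) {
  const int n = t.size();
  if (n < 3) stop("gaussian fit needs at least 3 points");

  // moment-based start values
  double ymin = R_PosInf, ymax = R_NegInf; int imax = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) { ymax = y[i]; imax = i; }
  }
  double wsum = 0.0, mu = 0.0;
  for (int i = 0; i < n; ++i) {
    double w = y[i] - ymin; if (w < 0) w = 0;
    wsum += w; mu += w * t[i];
  }
  double a = ymax, b, c;
  if (wsum > 0) {
    mu /= wsum;
    double var = 0.0;
    for (int i = 0; i < n; ++i) {
      double w = y[i] - ymin; if (w < 0) w = 0;
      var += w * (t[i] - mu) * (t[i] - mu);
    }
    var /= wsum;
    b = mu;
    c = std::sqrt(2.0 * std::max(var, 1.0));  // Var of exp(-(x/c)^2) shape is c^2/2
  } else {  // flat series: no usable weights
    b = t[imax];
    c = (t[n - 1] - t[0]) / 4.0 + 1.0;
  }
  if (a == 0.0) a = (ymax != 0.0) ? ymax : 1e-3;

  double lambda = 1e-3;
  double sse = model_sse(t, y, a, b, c);
  bool converged = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    // J^T J and J^T r for current (a, b, c)
    double JTJ[3][3] = {{0}}, JTr[3] = {0};
    for (int i = 0; i < n; ++i) {
      double z = (t[i] - b) / c;
      double e = std::exp(-z * z);
      double f = a * e;
      double r = y[i] - f;
      double J0 = e;                       // df/da
      double J1 = f * 2.0 * z / c;         // df/db
      double J2 = f * 2.0 * z * z / c;     // df/dc
      double J[3] = {J0, J1, J2};
      for (int p = 0; p < 3; ++p) {
        JTr[p] += J[p] * r;
        for (int q = p; q < 3; ++q) JTJ[p][q] += J[p] * J[q];
      }
    }
    JTJ[1][0] = JTJ[0][1]; JTJ[2][0] = JTJ[0][2]; JTJ[2][1] = JTJ[1][2];

    bool stepped = false;
    for (int attempt = 0; attempt < 30 && !stepped; ++attempt) {
      double A[3][3], rhs[3], d[3];
      for (int p = 0; p < 3; ++p) {
        rhs[p] = JTr[p];
        for (int q = 0; q < 3; ++q) A[p][q] = JTJ[p][q];
        A[p][p] *= (1.0 + lambda);
      }
      // Gaussian elimination with partial pivoting on the 3x3 system
      int piv[3] = {0, 1, 2};
      bool singular = false;
      for (int col = 0; col < 3 && !singular; ++col) {
        int best = col;
        for (int rrow = col + 1; rrow < 3; ++rrow)
          if (std::fabs(A[piv[rrow]][col]) > std::fabs(A[piv[best]][col])) best = rrow;
        std::swap(piv[col], piv[best]);
        double pv = A[piv[col]][col];
        if (std::fabs(pv) < 1e-300) { singular = true; break; }
        for (int rrow = col + 1; rrow < 3; ++rrow) {
          double fmul = A[piv[rrow]][col] / pv;
          for (int cc = col; cc < 3; ++cc) A[piv[rrow]][cc] -= fmul * A[piv[col]][cc];
          rhs[piv[rrow]] -= fmul * rhs[piv[col]];
        }
      }
      if (singular) { lambda *= 10.0; continue; }
      for (int col = 2; col >= 0; --col) {
        double s = rhs[piv[col]];
        for (int cc = col + 1; cc < 3; ++cc) s -= A[piv[col]][cc] * d[cc];
        d[col] = s / A[piv[col]][col];
      }
      double a2 = a + d[0], b2 = b + d[1], c2 = c + d[2];
      if (!std::isfinite(a2) || !std::isfinite(b2) || !std::isfinite(c2) ||
          std::fabs(c2) < 1e-8) { lambda *= 10.0; continue; }
      double sse2 = model_sse(t, y, a2, b2, c2);
      if (sse2 <= sse) {
        double rel = (sse - sse2) / (sse + 1e-300);
        a = a2; b = b2; c = c2; sse = sse2;
        lambda = std::max(lambda * 0.3, 1e-12);
        stepped = true;
        if (rel < tol) { converged = true; }
      } else {
        lambda *= 10.0;
      }
    }
    if (!stepped) { converged = (iter > 0); break; }  // stalled: accept if moved
    if (converged) break;
  }
  if (c < 0) c = -c;  // c enters squared; canonicalize sign
  return NumericVector::create(a, b, c, sse, converged ? 1.0 : 0.0);
}
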