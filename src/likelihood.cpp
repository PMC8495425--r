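#include <Rcpp.h>
#include <cmath>
#include <vector>

// Log-likelihood of a displacement pair (dx, dy) under a symmetric
// tridiagonal Toeplitz covariance (diagonal a, off-diagonal b), in the
// convention L = -log|S| - 0.5 dx' S^-1 dx - 0.5 dy' S^-1 dy (no 2*pi
// constant). Uses the LDL' factorization: d_1 = a, d_i = a - b^2/d_{i-1};
// the quadratic form follows from the unit-bidiagonal forward solve, so
// the cost is O(N) with no dense inverse. Returns NA when the
// factorization hits a non-positive pivot (matrix not positive definite).
// [[Rcpp::export]]
double tridiag_loglik_cpp(double a, double b,
                          Rcpp::NumericVector dx, Rcpp::NumericVector dy) {
  const int n = dx.size();
  if (n == 0 || dy.size() != n) return NA_REAL;
  double logdet = 0.0, qx = 0.0, qy = 0.0;
  double dprev = 0.0, exprev = 0.0, eyprev = 0.0;
  for (int i = 0; i < n; ++i) {
    double di, ex, ey;
    if (i == 0) {
      di = a; ex = dx[0]; ey = dy[0];
    } else {
      const double l = b / dprev;
      di = a - b * l;
      ex = dx[i] - l * exprev;
      ey = dy[i] - l * eyprev;
    }
    if (!(di > 0.0)) return NA_REAL;
    logdet += std::log(di);
    qx += ex * ex / di;
    qy += ey * ey / di;
    dprev = di; exprev = ex; eyprev = ey;
  }
  return -logdet - 0.5 * qx - 0.5 * qy;
}

namespace {

struct NegLL {
  const Rcpp::NumericVector& dx;
  const Rcpp::NumericVector& dy;
  double dt, R, logD_lo, logD_hi, s_hi;

  // objective over (logD, s); sigma2 = s^2; parameters clamped to their
  // bounds (flat outside), so the simplex may wander but the reported
  // optimum respects the box
  double operator()(double logD, double s) const {
    if (logD < logD_lo) logD = logD_lo;
    if (logD > logD_hi) logD = logD_hi;
    double sa = std::fabs(s);
    if (sa > s_hi) sa = s_hi;
    const double D = std::exp(logD);
    const double sigma2 = sa * sa;
    const double b = 2.0 * D * R * dt - sigma2;
    const double a = 2.0 * D * dt - 2.0 * b;
    const double L = tridiag_loglik_cpp(a, b, dx, dy);
    if (Rcpp::NumericVector::is_na(L)) return 1e12;
    return -L;
  }
};

// standard Nelder-Mead on 2 parameters; returns true when the simplex
// contracted below tol before maxit
bool nelder_mead_2d(const NegLL& f, double* par, double* val,
                    int maxit, double tol) {
  double p[3][2], y[3];
  const double step0 = 0.5, step1 = 0.02;
  p[0][0] = par[0];         p[0][1] = par[1];
  p[1][0] = par[0] + step0; p[1][1] = par[1];
  p[2][0] = par[0];         p[2][1] = par[1] + step1;
  for (int i = 0; i < 3; ++i) y[i] = f(p[i][0], p[i][1]);
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (y[i] < y[lo]) lo = i;
      if (y[i] > y[hi]) hi = i;
    }
    if (hi == lo) hi = (lo + 1) % 3;
    const int nh = 3 - lo - hi;  // second-worst vertex
    if (std::fabs(y[hi] - y[lo]) <=
        tol * (std::fabs(y[hi]) + std::fabs(y[lo]) + 1e-10)) {
      conv = true;
      break;
    }
    double c0 = 0.0, c1 = 0.0;
    for (int i = 0; i < 3; ++i) if (i != hi) { c0 += p[i][0]; c1 += p[i][1]; }
    c0 *= 0.5; c1 *= 0.5;
    // reflect
    double r0 = c0 + (c0 - p[hi][0]), r1 = c1 + (c1 - p[hi][1]);
    double yr = f(r0, r1);
    if (yr < y[lo]) {
      // expand
      double e0 = c0 + 2.0 * (c0 - p[hi][0]), e1 = c1 + 2.0 * (c1 - p[hi][1]);
      double ye = f(e0, e1);
      if (ye < yr) { p[hi][0] = e0; p[hi][1] = e1; y[hi] = ye; }
      else { p[hi][0] = r0; p[hi][1] = r1; y[hi] = yr; }
    } else if (yr < y[nh]) {
      p[hi][0] = r0; p[hi][1] = r1; y[hi] = yr;
    } else {
      // contract
      double k0 = c0 + 0.5 * (p[hi][0] - c0), k1 = c1 + 0.5 * (p[hi][1] - c1);
      double yk = f(k0, k1);
      if (yk < y[hi]) { p[hi][0] = k0; p[hi][1] = k1; y[hi] = yk; }
      else {
        // shrink toward best
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          p[i][0] = p[lo][0] + 0.5 * (p[i][0] - p[lo][0]);
          p[i][1] = p[lo][1] + 0.5 * (p[i][1] - p[lo][1]);
          y[i] = f(p[i][0], p[i][1]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (y[i] < y[lo]) lo = i;
  par[0] = p[lo][0]; par[1] = p[lo][1]; *val = y[lo];
  return conv;
}

} // namespace

// Multi-start maximizer of the exact (tridiagonal) displacement
// likelihood over (log D, s), sigma^2 = s^2. `starts` is a k x 2 matrix
// of (logD, s) starting points. Returns (logD, s, -negll, converged,
// n_starts_ok); ties in the objective below 1e-6 break toward smaller D.
// [[Rcpp::export]]
Rcpp::NumericVector fit_mle_exact_cpp(Rcpp::NumericVector dx,
                                      Rcpp::NumericVector dy,
                                      double dt, double R,
                                      Rcpp::NumericMatrix starts,
                                      double logD_lo, double logD_hi,
                                      double s_hi,
                                      int maxit, double tol) {
  NegLL f{dx, dy, dt, R, logD_lo, logD_hi, s_hi};
  double best_par[2] = {NA_REAL, NA_REAL};
  double best_val = R_PosInf;
  bool any_conv = false;
  int n_ok = 0;
  for (int k = 0; k < starts.nrow(); ++k) {
    double par[2] = {starts(k, 0), starts(k, 1)};
    double val;
    bool conv = nelder_mead_2d(f, par, &val, maxit, tol);
    if (!R_finite(val) || val >= 1e12) continue;
    ++n_ok;
    any_conv = any_conv || conv;
    // clamp to the box before comparing D
    if (par[0] < logD_lo) par[0] = logD_lo;
    if (par[0] > logD_hi) par[0] = logD_hi;
    if (val < best_val - 1e-6 ||
        (std::fabs(val - best_val) <= 1e-6 && par[0] < best_par[0])) {
      best_val = val;
      best_par[0] = par[0];
      best_par[1] = par[1];
    }
  }
  return Rcpp::NumericVector::create(best_par[0], best_par[1],
                                     -best_val, any_conv ? 1.0 : 0.0,
                                     (double)n_ok);
}

// Per-frame localization count within `eps` (3D Euclidean) for DBSCAN:
// brute-force O(n^2) neighbor counting, including the point itself.
// [[Rcpp::export]]
Rcpp::IntegerVector neighbor_counts_cpp(Rcpp::NumericMatrix pts, double eps) {
  const int n = pts.nrow();
  const double e2 = eps * eps;
  Rcpp::IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < pts.ncol(); ++k) {
        const double d = pts(i, k) - pts(j, k);
        s += d * d;
      }
      if (s <= e2) ++c;
    }
    out[i] = c;
  }
  return out;
}
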