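#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of a vector (modifies its argument).
static double median_of(std::vector<double> &v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Tukey biweight transform a_i = (x_i - med) * w_i with
// u_i = (x_i - med) / (9 * MAD), w_i = (1 - u_i^2)^2 * 1[|u_i| < 1].
// MAD is the unscaled median absolute deviation.  Returns false (Pearson
// fallback request) when MAD == 0.
static bool biweight_transform(const std::vector<double> &x,
                               std::vector<double> &a) {
  const size_t n = x.size();
  std::vector<double> tmp(x);
  const double med = median_of(tmp);
  for (size_t i = 0; i < n; ++i) tmp[i] = std::fabs(x[i] - med);
  const double mad = median_of(tmp);
  if (mad == 0.0) return false;
  a.resize(n);
  for (size_t i = 0; i < n; ++i) {
    const double u = (x[i] - med) / (9.0 * mad);
    double w = 0.0;
    if (std::fabs(u) < 1.0) {
      const double q = 1.0 - u * u;
      w = q * q;
    }
    a[i] = (x[i] - med) * w;
  }
  return true;
}

// Pearson-style mean-centering (fallback when MAD == 0).
static void center_transform(const std::vector<double> &x,
                             std::vector<double> &a) {
  const size_t n = x.size();
  double m = 0.0;
  for (size_t i = 0; i < n; ++i) m += x[i];
  m /= (double)n;
  a.resize(n);
  for (size_t i = 0; i < n; ++i) a[i] = x[i] - m;
}

// Correlation of two complete vectors; method_out: 0 = bicor, 1 = pearson.
static double bicor_complete(const std::vector<double> &x,
                             const std::vector<double> &y, int &method_out) {
  std::vector<double> a, b;
  const bool okx = biweight_transform(x, a);
  const bool oky = biweight_transform(y, b);
  if (!okx || !oky) {
    center_transform(x, a);
    center_transform(y, b);
    method_out = 1;
  } else {
    method_out = 0;
  }
  double sab = 0.0, saa = 0.0, sbb = 0.0;
  for (size_t i = 0; i < a.size(); ++i) {
    sab += a[i] * b[i];
    saa += a[i] * a[i];
    sbb += b[i] * b[i];
  }
  if (saa == 0.0 || sbb == 0.0) return NA_REAL;
  double r = sab / std::sqrt(saa * sbb);
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  return r;
}

// Pairwise-complete bicor between columns of X and columns of Y
// (rows = samples).  Per pair, rows with a missing value in either column
// are dropped before medians/MADs are computed.
// [[Rcpp::export]]
List bicor_cross_cpp(NumericMatrix X, NumericMatrix Y, int min_n) {
  const int n = X.nrow(), p = X.ncol(), q = Y.ncol();
  if (Y.nrow() != n) stop("X and Y must have the same number of rows");
  NumericMatrix R(p, q);
  IntegerMatrix N(p, q), M(p, q);
  std::vector<double> x, y;
  x.reserve(n);
  y.reserve(n);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < q; ++j) {
      x.clear();
      y.clear();
      for (int k = 0; k < n; ++k) {
        const double xv = X(k, i), yv = Y(k, j);
        if (!ISNAN(xv) && !ISNAN(yv)) {
          x.push_back(xv);
          y.push_back(yv);
        }
      }
      N(i, j) = (int)x.size();
      if ((int)x.size() < min_n) {
        R(i, j) = NA_REAL;
        M(i, j) = NA_INTEGER;
      } else {
        int meth = 0;
        R(i, j) = bicor_complete(x, y, meth);
        M(i, j) = meth;
      }
    }
  }
  return List::create(_["r"] = R, _["n"] = N, _["method"] = M);
}

// Symmetric pairwise-complete bicor of the columns of X.
// [[Rcpp::export]]
List bicor_self_cpp(NumericMatrix X, int min_n) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix R(p, p);
  IntegerMatrix N(p, p), M(p, p);
  std::vector<double> x, y;
  x.reserve(n);
  y.reserve(n);
  for (int i = 0; i < p; ++i) {
    R(i, i) = 1.0;
    M(i, i) = 0;
    int ni = 0;
    for (int k = 0; k < n; ++k)
      if (!ISNAN(X(k, i))) ++ni;
    N(i, i) = ni;
    for (int j = i + 1; j < p; ++j) {
      x.clear();
      y.clear();
      for (int k = 0; k < n; ++k) {
        const double xv = X(k, i), yv = X(k, j);
        if (!ISNAN(xv) && !ISNAN(yv)) {
          x.push_back(xv);
          y.push_back(yv);
        }
      }
      N(i, j) = N(j, i) = (int)x.size();
      if ((int)x.size() < min_n) {
        R(i, j) = R(j, i) = NA_REAL;
        M(i, j) = M(j, i) = NA_INTEGER;
      } else {
        int meth = 0;
        const double r = bicor_complete(x, y, meth);
        R(i, j) = R(j, i) = r;
        M(i, j) = M(j, i) = meth;
      }
    }
  }
  return List::create(_["r"] = R, _["n"] = N, _["method"] = M);
}
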