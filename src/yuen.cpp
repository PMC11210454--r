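#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Yuen-Welch T on already-extracted groups. Convention for the degenerate
// zero-variance case: equal trimmed means -> 0, unequal -> +/-Inf (the
// permutation caller treats |Inf| as exceeding any finite observation).
static double yuen_T(std::vector<double>& x, std::vector<double>& y,
                     double trim) {
  const int nx = x.size(), ny = y.size();
  std::sort(x.begin(), x.end());
  std::sort(y.begin(), y.end());
  const int gx = (int)std::floor(trim * nx), gy = (int)std::floor(trim * ny);
  const int hx = nx - 2 * gx, hy = ny - 2 * gy;

  double tx = 0.0, ty = 0.0;
  for (int i = gx; i < nx - gx; ++i) tx += x[i];
  tx /= hx;
  for (int i = gy; i < ny - gy; ++i) ty += y[i];
  ty /= hy;

  // winsorized sample variance (divisor n-1)
  double mwx = 0.0, mwy = 0.0;
  for (int i = 0; i < nx; ++i) {
    double v = x[std::min(std::max(i, gx), nx - gx - 1)];
    mwx += v;
  }
  mwx /= nx;
  double s2x = 0.0;
  for (int i = 0; i < nx; ++i) {
    double v = x[std::min(std::max(i, gx), nx - gx - 1)] - mwx;
    s2x += v * v;
  }
  s2x /= (nx - 1);
  for (int i = 0; i < ny; ++i) {
    double v = y[std::min(std::max(i, gy), ny - gy - 1)];
    mwy += v;
  }
  mwy /= ny;
  double s2y = 0.0;
  for (int i = 0; i < ny; ++i) {
    double v = y[std::min(std::max(i, gy), ny - gy - 1)] - mwy;
    s2y += v * v;
  }
  s2y /= (ny - 1);

  const double dx = (nx - 1) * s2x / ((double)hx * (hx - 1));
  const double dy = (ny - 1) * s2y / ((double)hy * (hy - 1));
  const double diff = tx - ty;
  const double den = dx + dy;
  if (den <= 0.0) {
    if (diff == 0.0) return 0.0;
    return diff > 0.0 ? R_PosInf : R_NegInf;
  }
  return diff / std::sqrt(den);
}

// [[Rcpp::export(name = ".yuen_statistic_cpp")]]
double yuen_statistic_cpp(NumericVector x, NumericVector y, double trim) {
  std::vector<double> xs(x.begin(), x.end());
  std::vector<double> ys(y.begin(), y.end());
  return yuen_T(xs, ys, trim);
}

// B random relabelings of the pooled sample (group sizes preserved),
// returning |T| for each. Uses R's RNG so set.seed() governs the draws.
// [[Rcpp::export(name = ".perm_yuen_abs_cpp")]]
NumericVector perm_yuen_abs_cpp(NumericVector pooled, int nx, int B,
                                double trim) {
  const int n = pooled.size();
  const int ny = n - nx;
  NumericVector out(B);
  std::vector<double> work(pooled.begin(), pooled.end());
  std::vector<double> x(nx), y(ny);
  for (int b = 0; b < B; ++b) {
    // partial Fisher-Yates: first nx entries become the permuted case group
    for (int i = 0; i < nx; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(work[i], work[j]);
    }
    std::copy(work.begin(), work.begin() + nx, x.begin());
    std::copy(work.begin() + nx, work.end(), y.begin());
    out[b] = std::fabs(yuen_T(x, y, trim));
  }
  return out;
}
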