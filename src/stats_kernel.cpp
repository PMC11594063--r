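#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Core two-sample statistics computed in one merged pass over sorted inputs:
//  - Welch t statistic and Welch-Satterthwaite degrees of freedom
//  - Kolmogorov-Smirnov D = max |Fx - Fy|, evaluated after tie groups
//  - two-sample Anderson-Darling A2akN (Scholz-Stephens k-sample statistic,
//    midrank version for ties) and its standardized form
//    T = (A2akN - (k-1)) / sigma_N with the Scholz-Stephens variance.
// p-value computation stays on the R side.

namespace {

struct TwoSampleStats {
  double t, df, ksD, A2, T, sigma;
};

// Scholz-Stephens variance of A2akN under H0, k = 2
double ad_sigma(int n, int m) {
  const double k = 2.0;
  const double N = n + m;
  const double H = 1.0 / n + 1.0 / m;
  // harmonic prefix sums: hsum[i] = sum_{j=1}^{i} 1/j
  const int Ni = n + m;
  std::vector<double> hsum(Ni, 0.0);
  for (int i = 1; i < Ni; ++i) hsum[i] = hsum[i - 1] + 1.0 / i;
  const double h = hsum[Ni - 1];
  // g = sum_{i=1}^{N-2} sum_{j=i+1}^{N-1} 1/((N-i) j)
  //   = sum_{i=1}^{N-2} (h(N-1) - h(i)) / (N-i)
  double g = 0.0;
  for (int i = 1; i <= Ni - 2; ++i) g += (hsum[Ni - 1] - hsum[i]) / (Ni - i);
  const double a = (4.0 * g - 6.0) * (k - 1.0) + (10.0 - 6.0 * g) * H;
  const double b = (2.0 * g - 4.0) * k * k + 8.0 * h * k +
                   (2.0 * g - 14.0 * h - 4.0) * H - 8.0 * h + 4.0 * g - 6.0;
  const double c = (6.0 * h + 2.0 * g - 2.0) * k * k +
                   (4.0 * h - 4.0 * g + 6.0) * k + (2.0 * h - 6.0) * H +
                   4.0 * h;
  const double d = (2.0 * h + 6.0) * k * k - 4.0 * h * k;
  const double var =
      (a * N * N * N + b * N * N + c * N + d) /
      ((N - 1.0) * (N - 2.0) * (N - 3.0));
  return std::sqrt(var);
}

// xs, ys must be sorted ascending
TwoSampleStats core(const double *xs, int n, const double *ys, int m) {
  TwoSampleStats s;
  const double N = n + m;

  // Welch from moments
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) mx += xs[i];
  for (int j = 0; j < m; ++j) my += ys[j];
  mx /= n;
  my /= m;
  double vx = 0, vy = 0;
  for (int i = 0; i < n; ++i) vx += (xs[i] - mx) * (xs[i] - mx);
  for (int j = 0; j < m; ++j) vy += (ys[j] - my) * (ys[j] - my);
  vx /= (n - 1);
  vy /= (m - 1);
  const double se2 = vx / n + vy / m;
  if (se2 > 0) {
    s.t = (mx - my) / std::sqrt(se2);
    s.df = se2 * se2 /
           ((vx / n) * (vx / n) / (n - 1) + (vy / m) * (vy / m) / (m - 1));
  } else {
    // both samples constant: equal means -> no evidence; else infinite t
    s.t = (mx == my) ? 0.0 : (mx > my ? R_PosInf : R_NegInf);
    s.df = n + m - 2.0;
  }

  // merged pass: KS D and AD A2akN (midrank) over tie groups
  double D = 0.0, A2x = 0.0, A2y = 0.0;
  int i = 0, j = 0;
  double cx = 0, cy = 0;  // cumulative counts through current tie group
  bool all_tied = true;
  double first_val = (n > 0) ? xs[0] : ys[0];
  while (i < n || j < m) {
    double v;
    if (i < n && (j >= m || xs[i] <= ys[j])) v = xs[i];
    else v = ys[j];
    if (v != first_val) all_tied = false;
    int fx = 0, fy = 0;
    while (i < n && xs[i] == v) { ++i; ++fx; }
    while (j < m && ys[j] == v) { ++j; ++fy; }
    const double l = fx + fy;
    const double B = cx + cy + l;         // pooled count through group
    const double Baj = B - l / 2.0;       // midrank pooled count
    const double Mx = cx + fx / 2.0;      // midrank count, sample x
    const double My = cy + fy / 2.0;
    const double denom = Baj * (N - Baj) - N * l / 4.0;
    if (denom > 0) {
      const double tx = N * Mx - n * Baj;
      const double ty = N * My - m * Baj;
      A2x += (l / N) * tx * tx / denom;
      A2y += (l / N) * ty * ty / denom;
    }
    cx += fx;
    cy += fy;
    const double d = std::fabs(cx / n - cy / m);
    if (d > D) D = d;
  }
  s.ksD = D;
  if (all_tied) {
    s.A2 = 0.0;
  } else {
    s.A2 = (N - 1.0) / N * (A2x / n + A2y / m);
  }
  s.sigma = ad_sigma(n, m);
  s.T = (s.A2 - 1.0) / s.sigma;  // k - 1 = 1
  return s;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_two_sample_stats(NumericVector x, NumericVector y) {
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::sort(xs.begin(), xs.end());
  std::sort(ys.begin(), ys.end());
  TwoSampleStats s = core(xs.data(), (int)xs.size(), ys.data(), (int)ys.size());
  return NumericVector::create(
      _["t"] = s.t, _["df"] = s.df, _["ksD"] = s.ksD, _["A2"] = s.A2,
      _["T"] = s.T, _["sigma"] = s.sigma);
}

// Resampling loop: ix, iy are n_iter x n_points matrices of 1-based indices
// into x and y. Returns an n_iter x 4 matrix (t, df, ksD, T_AD).
// [[Rcpp::export]]
NumericMatrix cpp_resample_kernel(NumericVector x, NumericVector y,
                                  IntegerMatrix ix, IntegerMatrix iy) {
  const int n_iter = ix.nrow();
  const int np_x = ix.ncol(), np_y = iy.ncol();
  NumericMatrix out(n_iter, 4);
  std::vector<double> xs(np_x), ys(np_y);
  for (int it = 0; it < n_iter; ++it) {
    for (int c = 0; c < np_x; ++c) xs[c] = x[ix(it, c) - 1];
    for (int c = 0; c < np_y; ++c) ys[c] = y[iy(it, c) - 1];
    std::sort(xs.begin(), xs.end());
    std::sort(ys.begin(), ys.end());
    TwoSampleStats s = core(xs.data(), np_x, ys.data(), np_y);
    out(it, 0) = s.t;
    out(it, 1) = s.df;
    out(it, 2) = s.ksD;
    out(it, 3) = s.T;
  }
  return out;
}
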