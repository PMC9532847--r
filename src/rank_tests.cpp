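#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// average ranks with midranks for ties; v is copied
static void avg_ranks(const std::vector<double>& v, std::vector<double>& r,
                      double& tiesum) {
  int n = v.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  tiesum = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    double rank = 0.5 * (i + j) + 1.0;
    int t = j - i + 1;
    if (t > 1) tiesum += (double)t * t * t - t;
    for (int k = i; k <= j; ++k) r[idx[k]] = rank;
    i = j + 1;
  }
}

static double median_of(std::vector<double> v) {
  int n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.end());
  return 0.5 * (v[n / 2 - 1] + hi);
}

// Row-wise two-tailed Wilcoxon rank-sum p-values (normal approximation,
// tie and continuity correction). idx1 holds 1-based column indices of
// the first group.
// [[Rcpp::export(name = ".wilcoxon_rows_cpp")]]
NumericVector wilcoxon_rows_cpp(NumericMatrix x, IntegerVector idx1) {
  int m = x.nrow(), n = x.ncol(), n1 = idx1.size();
  int n2 = n - n1;
  std::vector<bool> in1(n, false);
  for (int k = 0; k < n1; ++k) in1[idx1[k] - 1] = true;
  NumericVector p(m);
  std::vector<double> v(n), r(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) v[j] = x(i, j);
    double tiesum;
    avg_ranks(v, r, tiesum);
    double rs = 0.0;
    for (int j = 0; j < n; ++j) if (in1[j]) rs += r[j];
    double W = rs - 0.5 * n1 * (n1 + 1.0);
    double mu = 0.5 * n1 * n2;
    double sigma2 = (double)n1 * n2 / 12.0 *
      ((n + 1.0) - tiesum / ((double)n * (n - 1.0)));
    if (sigma2 <= 0.0) { p[i] = 1.0; continue; }
    double z = W - mu;
    double corr = (z > 0) ? 0.5 : ((z < 0) ? -0.5 : 0.0);
    z = (z - corr) / std::sqrt(sigma2);
    double pv = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
    p[i] = pv < 1.0 ? pv : 1.0;
  }
  return p;
}

// Wilcoxon p for one row given precomputed full-row ranks and tiesum.
static double wilcox_p_from_ranks(const std::vector<double>& r,
                                  const std::vector<bool>& in1,
                                  int n, int n1, double tiesum) {
  int n2 = n - n1;
  double rs = 0.0;
  for (int j = 0; j < n; ++j) if (in1[j]) rs += r[j];
  double W = rs - 0.5 * n1 * (n1 + 1.0);
  double mu = 0.5 * n1 * n2;
  double sigma2 = (double)n1 * n2 / 12.0 *
    ((n + 1.0) - tiesum / ((double)n * (n - 1.0)));
  if (sigma2 <= 0.0) return 1.0;
  double z = W - mu;
  double corr = (z > 0) ? 0.5 : ((z < 0) ? -0.5 : 0.0);
  z = (z - corr) / std::sqrt(sigma2);
  double pv = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
  return pv < 1.0 ? pv : 1.0;
}

// Fligner-Killeen p for one row over the columns listed in cols (first
// n1 of them form group 1). qn is a lookup of qnorm((1 + k/(nc+1))/2)
// for integer k; midranks interpolate between entries.
static double fligner_p_cols(const double* xrow, const std::vector<int>& cols,
                             int n1, std::vector<double>& g1,
                             std::vector<double>& g2,
                             std::vector<double>& dev,
                             std::vector<double>& r) {
  int nc = cols.size();
  int n2 = nc - n1;
  g1.resize(n1); g2.resize(n2); dev.resize(nc); r.resize(nc);
  for (int j = 0; j < n1; ++j) g1[j] = xrow[cols[j]];
  for (int j = 0; j < n2; ++j) g2[j] = xrow[cols[n1 + j]];
  double m1 = median_of(g1), m2 = median_of(g2);
  for (int j = 0; j < nc; ++j)
    dev[j] = std::fabs(xrow[cols[j]] - (j < n1 ? m1 : m2));
  double tiesum;
  avg_ranks(dev, r, tiesum);
  double asum = 0.0, ss = 0.0, s1 = 0.0, s2 = 0.0;
  std::vector<double> a(nc);
  for (int j = 0; j < nc; ++j) {
    a[j] = R::qnorm(0.5 * (1.0 + r[j] / (nc + 1.0)), 0.0, 1.0, 1, 0);
    asum += a[j];
  }
  double abar = asum / nc;
  for (int j = 0; j < nc; ++j) {
    ss += (a[j] - abar) * (a[j] - abar);
    if (j < n1) s1 += a[j]; else s2 += a[j];
  }
  double v2 = ss / (nc - 1.0);
  if (v2 <= 1e-10) return 1.0;   // degenerate scores (e.g. constant row)
  double mb1 = s1 / n1, mb2 = s2 / n2;
  double stat = (n1 * (mb1 - abar) * (mb1 - abar) +
                 n2 * (mb2 - abar) * (mb2 - abar)) / v2;
  return R::pchisq(stat, 1.0, 0, 0);
}

// Label-shuffle driver: counts, per row, how many permutations give a
// Wilcoxon (resp. Fligner) p strictly below the observed one. idx_mat is
// n1 x B with 1-based column indices of the permuted "high" group.
// Full-row Wilcoxon ranks are permutation-invariant and precomputed.
// [[Rcpp::export(name = ".shuffle_counts_cpp")]]
List shuffle_counts_cpp(NumericMatrix x, IntegerMatrix idx_mat,
                        NumericVector obs_w, NumericVector obs_f) {
  int m = x.nrow(), n = x.ncol(), n1 = idx_mat.nrow(), B = idx_mat.ncol();
  std::vector<std::vector<double> > ranks(m, std::vector<double>(n));
  std::vector<double> tiesums(m);
  std::vector<double> v(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) v[j] = x(i, j);
    avg_ranks(v, ranks[i], tiesums[i]);
  }
  IntegerVector cw(m), cf(m);
  std::vector<bool> in1(n);
  std::vector<int> cols(n);
  std::vector<double> g1, g2, dev, r;
  std::vector<const double*> rowptr(m);
  NumericMatrix xt = transpose(x);   // rows contiguous
  for (int b = 0; b < B; ++b) {
    std::fill(in1.begin(), in1.end(), false);
    for (int k = 0; k < n1; ++k) in1[idx_mat(k, b) - 1] = true;
    int c = 0;
    for (int k = 0; k < n1; ++k) cols[c++] = idx_mat(k, b) - 1;
    for (int j = 0; j < n; ++j) if (!in1[j]) cols[c++] = j;
    for (int i = 0; i < m; ++i) {
      double pw = wilcox_p_from_ranks(ranks[i], in1, n, n1, tiesums[i]);
      if (pw < obs_w[i]) ++cw[i];
      double pf = fligner_p_cols(&xt(0, i), cols, n1, g1, g2, dev, r);
      if (pf < obs_f[i]) ++cf[i];
    }
  }
  return List::create(_["wilcox"] = cw, _["fligner"] = cf);
}

// Down-sampling driver: the high group (hi_idx) is fixed; each column of
// sub_mat holds the drawn rest-group columns (1-based). Counts, per row,
// the iterations with p < alpha for each test.
// [[Rcpp::export(name = ".downsample_counts_cpp")]]
List downsample_counts_cpp(NumericMatrix x, IntegerVector hi_idx,
                           IntegerMatrix sub_mat, double alpha) {
  int m = x.nrow(), n1 = hi_idx.size(), B = sub_mat.ncol();
  int ns = sub_mat.nrow();
  int nc = n1 + ns;
  IntegerVector cw(m), cf(m);
  std::vector<int> cols(nc);
  std::vector<double> vv(nc), rr(nc);
  std::vector<bool> in1(nc, false);
  for (int j = 0; j < n1; ++j) in1[j] = true;
  std::vector<double> g1, g2, dev, r;
  NumericMatrix xt = transpose(x);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < n1; ++k) cols[k] = hi_idx[k] - 1;
    for (int k = 0; k < ns; ++k) cols[n1 + k] = sub_mat(k, b) - 1;
    for (int i = 0; i < m; ++i) {
      const double* xrow = &xt(0, i);
      for (int j = 0; j < nc; ++j) vv[j] = xrow[cols[j]];
      double tiesum;
      avg_ranks(vv, rr, tiesum);
      double pw = wilcox_p_from_ranks(rr, in1, nc, n1, tiesum);
      if (pw < alpha) ++cw[i];
      double pf = fligner_p_cols(xrow, cols, n1, g1, g2, dev, r);
      if (pf < alpha) ++cf[i];
    }
  }
  return List::create(_["wilcox"] = cw, _["fligner"] = cf);
}

// Row-wise Fligner-Killeen scale-test p-values (two groups, normal
// scores, chi-square with 1 df).
// [[Rcpp::export(name = ".fligner_rows_cpp")]]
NumericVector fligner_rows_cpp(NumericMatrix x, IntegerVector idx1) {
  int m = x.nrow(), n = x.ncol(), n1 = idx1.size();
  int n2 = n - n1;
  std::vector<bool> in1(n, false);
  for (int k = 0; k < n1; ++k) in1[idx1[k] - 1] = true;
  NumericVector p(m);
  std::vector<double> g1(n1), g2(n2), dev(n), r(n), a(n);
  for (int i = 0; i < m; ++i) {
    int c1 = 0, c2 = 0;
    for (int j = 0; j < n; ++j) {
      if (in1[j]) g1[c1++] = x(i, j); else g2[c2++] = x(i, j);
    }
    double m1 = median_of(g1), m2 = median_of(g2);
    for (int j = 0; j < n; ++j)
      dev[j] = std::fabs(x(i, j) - (in1[j] ? m1 : m2));
    double tiesum;
    avg_ranks(dev, r, tiesum);
    double asum = 0.0;
    for (int j = 0; j < n; ++j) {
      a[j] = R::qnorm(0.5 * (1.0 + r[j] / (n + 1.0)), 0.0, 1.0, 1, 0);
      asum += a[j];
    }
    double abar = asum / n;
    double ss = 0.0;
    for (int j = 0; j < n; ++j) ss += (a[j] - abar) * (a[j] - abar);
    double v2 = ss / (n - 1.0);
    if (v2 <= 1e-10) { p[i] = 1.0; continue; }   // degenerate scores
    double s1 = 0.0, s2 = 0.0;
    for (int j = 0; j < n; ++j) { if (in1[j]) s1 += a[j]; else s2 += a[j]; }
    double mbar1 = s1 / n1, mbar2 = s2 / n2;
    double stat = (n1 * (mbar1 - abar) * (mbar1 - abar) +
                   n2 * (mbar2 - abar) * (mbar2 - abar)) / v2;
    p[i] = R::pchisq(stat, 1.0, 0, 0);
  }
  return p;
}
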