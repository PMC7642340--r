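#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Local Smith-Waterman with linear gap cost and score floor 0.
// [[Rcpp::export]]
int cpp_sw_local(const std::string& a, const std::string& b,
                 int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int v = prev[j - 1] + s;
      if (prev[j] + gap > v) v = prev[j] + gap;
      if (cur[j - 1] + gap > v) v = cur[j - 1] + gap;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Semilocal ("glocal") alignment: the first sequence is aligned end-to-end,
// end gaps on the second sequence are free. Used to locate a barcode inside
// a longer read. No score floor.
// [[Rcpp::export]]
int cpp_sw_semilocal(const std::string& a, const std::string& b,
                     int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  const int NEG = -1000000000;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = 0;  // free start anywhere in b
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;  // gaps in b before a starts: a must be fully aligned
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int v = prev[j - 1] + s;
      if (prev[j] + gap > v) v = prev[j] + gap;
      if (cur[j - 1] + gap > v) v = cur[j - 1] + gap;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  int best = NEG;
  for (int j = 0; j <= m; ++j) if (prev[j] > best) best = prev[j];
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_sw_vs_set(const std::string& a, const CharacterVector& set,
                            int match, int mismatch, int gap) {
  const int n = set.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cpp_sw_local(a, std::string(set[i]), match, mismatch, gap);
  return out;
}

// DTW with steps (i-1,j), (i,j-1), (i-1,j-1), local cost |a-b|.
// Returns total cost and the length of the optimal warping path
// (tie-break: diagonal, then (i-1,j), then (i,j-1)).
// [[Rcpp::export]]
List cpp_dtw(const NumericVector& x, const NumericVector& y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty signal in DTW");
  std::vector<double> dprev(m), dcur(m);
  std::vector<int> lprev(m), lcur(m);
  dprev[0] = std::fabs(x[0] - y[0]);
  lprev[0] = 1;
  for (int j = 1; j < m; ++j) {
    dprev[j] = dprev[j - 1] + std::fabs(x[0] - y[j]);
    lprev[j] = j + 1;
  }
  for (int i = 1; i < n; ++i) {
    dcur[0] = dprev[0] + std::fabs(x[i] - y[0]);
    lcur[0] = i + 1;
    for (int j = 1; j < m; ++j) {
      double c = std::fabs(x[i] - y[j]);
      double bd = dprev[j - 1];
      int bl = lprev[j - 1];
      if (dprev[j] < bd) { bd = dprev[j]; bl = lprev[j]; }
      if (dcur[j - 1] < bd) { bd = dcur[j - 1]; bl = lcur[j - 1]; }
      dcur[j] = bd + c;
      lcur[j] = bl + 1;
    }
    std::swap(dprev, dcur);
    std::swap(lprev, lcur);
  }
  return List::create(_["cost"] = dprev[m - 1],
                      _["path_length"] = lprev[m - 1]);
}

// [[Rcpp::export]]
NumericVector cpp_dtw_vs_set(const NumericVector& x, const List& ys) {
  const int n = ys.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    NumericVector y = ys[i];
    List r = cpp_dtw(x, y);
    out[i] = as<double>(r["cost"]) / as<int>(r["path_length"]);
  }
  return out;
}
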