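#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdlib>

using namespace Rcpp;

// Strings arrive as 0-based alphabet codes (see .string_codes in R).
// All distances return plain integers; positions are 1-based as in the
// ranking formulation.

// Rank distance, linear-time path. The annotated i-th occurrence of a
// letter in x pairs with the i-th occurrence of the same letter in y; each
// symbol carries its order ord = n + 1 - position (n the length of its own
// string; the first symbol has the highest order), a symbol absent from a
// string has order 0 there, and the distance is the L1 distance between
// the two order vectors. For equal-length strings a paired symbol thus
// contributes |pos_x - pos_y| and an unpaired one n + 1 - pos.
// [[Rcpp::export(name = ".cpp_rank_distance")]]
double cpp_rank_distance(const IntegerVector& x, const IntegerVector& y,
                         const int k) {
  std::vector<std::vector<int> > px(k), py(k);
  const int nx = x.size(), ny = y.size();
  for (int i = 0; i < nx; ++i) px[x[i]].push_back(i + 1);
  for (int i = 0; i < ny; ++i) py[y[i]].push_back(i + 1);
  double d = 0.0;
  for (int a = 0; a < k; ++a) {
    const std::vector<int>& u = px[a];
    const std::vector<int>& v = py[a];
    const size_t m = std::min(u.size(), v.size());
    for (size_t i = 0; i < m; ++i)
      d += std::abs((nx + 1 - u[i]) - (ny + 1 - v[i]));
    for (size_t i = m; i < u.size(); ++i) d += nx + 1 - u[i];
    for (size_t i = m; i < v.size(); ++i) d += ny + 1 - v[i];
  }
  return d;
}

// [[Rcpp::export(name = ".cpp_hamming")]]
double cpp_hamming(const IntegerVector& x, const IntegerVector& y) {
  const int n = x.size();
  int d = 0;
  for (int i = 0; i < n; ++i)
    if (x[i] != y[i]) ++d;
  return d;
}

static int lev_codes(const int* x, int nx, const int* y, int ny) {
  if (nx == 0) return ny;
  if (ny == 0) return nx;
  std::vector<int> prev(ny + 1), cur(ny + 1);
  for (int j = 0; j <= ny; ++j) prev[j] = j;
  for (int i = 1; i <= nx; ++i) {
    cur[0] = i;
    for (int j = 1; j <= ny; ++j) {
      const int sub = prev[j - 1] + (x[i - 1] == y[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[ny];
}

// [[Rcpp::export(name = ".cpp_levenshtein")]]
double cpp_levenshtein(const IntegerVector& x, const IntegerVector& y) {
  return lev_codes(x.begin(), x.size(), y.begin(), y.size());
}

// Minimum distance from a fixed-length candidate to any contiguous window
// of the input, under metric 0 = rank, 1 = hamming, 2 = levenshtein.
// Windows have the candidate's length for every metric.
// [[Rcpp::export(name = ".cpp_min_window_distance")]]
double cpp_min_window_distance(const IntegerVector& chrom,
                               const IntegerVector& input,
                               const int metric, const int k) {
  const int L = chrom.size(), n = input.size();
  if (L > n) stop("candidate longer than input");
  const int nw = n - L + 1;
  double best = R_PosInf;
  // occurrence positions of the candidate, reused across windows
  std::vector<std::vector<int> > pc(k);
  if (metric == 0)
    for (int i = 0; i < L; ++i) pc[chrom[i]].push_back(i + 1);
  std::vector<std::vector<int> > pw(k);
  for (int w = 0; w < nw; ++w) {
    double d = 0.0;
    if (metric == 0) {
      // candidate and window have equal length L, so orders line up with
      // positions: paired |pos - pos|, unpaired L + 1 - pos
      for (int a = 0; a < k; ++a) pw[a].clear();
      for (int i = 0; i < L; ++i) pw[input[w + i]].push_back(i + 1);
      for (int a = 0; a < k; ++a) {
        const std::vector<int>& u = pc[a];
        const std::vector<int>& v = pw[a];
        const size_t m = std::min(u.size(), v.size());
        for (size_t i = 0; i < m; ++i) d += std::abs(u[i] - v[i]);
        for (size_t i = m; i < u.size(); ++i) d += L + 1 - u[i];
        for (size_t i = m; i < v.size(); ++i) d += L + 1 - v[i];
      }
    } else if (metric == 1) {
      for (int i = 0; i < L; ++i)
        if (chrom[i] != input[w + i]) ++d;
    } else {
      d = lev_codes(chrom.begin(), L, input.begin() + w, L);
    }
    if (d < best) best = d;
    if (best == 0.0) break;
  }
  return best;
}
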