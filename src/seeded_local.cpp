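#include <Rcpp.h>
#include <vector>
#include <string>

// Best-scoring local alignment of a and b constrained to contain an exact
// shared word of length w as w consecutive aligned matches (the "seed").
// Dynamic program over cells (i, j) with w+1 states: t = 0..w-1 tracks the
// trailing run of consecutive diagonal matches of a path that has not yet
// contained a full w-run; the extra state holds paths that have. A fresh
// local alignment may start at any cell (state t = 0 clamped at 0); the
// seeded state is never clamped, so the seed is never discarded. Equivalent
// to exhaustive seed-and-extend with the same match/mismatch/gap scores.
// Letters other than A,C,G,T never match (N vs N is a mismatch).

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
double seeded_local_score_cpp(std::string a, std::string b, int w,
                              double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  if (n == 0 || m == 0 || w < 1) return 0.0;

  // state layout: row[t * (m+1) + j] for t in 0..w-1, plus seeded row
  std::vector<double> prevN((size_t)w * (m + 1), NEG), curN(prevN);
  std::vector<double> prevS(m + 1, NEG), curS(m + 1, NEG);
  for (int j = 0; j <= m; ++j) prevN[j] = 0.0;  // t = 0, empty alignment

  double best = NEG;
  for (int i = 1; i <= n; ++i) {
    curN[0] = 0.0;
    for (int t = 1; t < w; ++t) curN[(size_t)t * (m + 1)] = NEG;
    curS[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1] && is_base(a[i - 1]);
      double diag_ns = NEG, up_ns = NEG, left_ns = NEG;
      for (int t = 0; t < w; ++t) {
        const size_t off = (size_t)t * (m + 1);
        if (prevN[off + j - 1] > diag_ns) diag_ns = prevN[off + j - 1];
        if (prevN[off + j] > up_ns) up_ns = prevN[off + j];
        if (curN[off + j - 1] > left_ns) left_ns = curN[off + j - 1];
      }
      double n0 = 0.0;  // start a fresh alignment here
      if (up_ns + gap > n0) n0 = up_ns + gap;
      if (left_ns + gap > n0) n0 = left_ns + gap;
      if (!eq && diag_ns + mismatch > n0) n0 = diag_ns + mismatch;
      curN[j] = n0;
      for (int t = 1; t < w; ++t) {
        const size_t off = (size_t)t * (m + 1);
        curN[off + j] =
            eq ? prevN[(size_t)(t - 1) * (m + 1) + j - 1] + match : NEG;
      }
      double s = prevS[j - 1] + (eq ? match : mismatch);
      if (prevS[j] + gap > s) s = prevS[j] + gap;
      if (curS[j - 1] + gap > s) s = curS[j - 1] + gap;
      if (eq) {
        const double from_run = prevN[(size_t)(w - 1) * (m + 1) + j - 1] + match;
        if (from_run > s) s = from_run;
      }
      curS[j] = s;
      if (s > best) best = s;
    }
    std::swap(prevN, curN);
    std::swap(prevS, curS);
  }
  return best > 0.0 ? best : 0.0;
}
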