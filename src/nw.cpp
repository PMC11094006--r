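#include <Rcpp.h>
#include <vector>
#include <string>

// Global (Needleman-Wunsch) alignment identity with match +1, mismatch -1,
// linear gap -2. Identity = matching columns / total alignment columns, so
// gap columns count as mismatches. Traceback ties prefer diagonal, then the
// gap in the shorter sequence, for determinism.

static const int MATCH = 1, MISMATCH = -1, GAP = -2;

static double nw_identity_one(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // direction: 0 diag, 1 up (gap in b), 2 left (gap in a)
  std::vector<unsigned char> dir((n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = GAP * j; dir[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = GAP * i;
    dir[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
      int u = prev[j] + GAP;
      int l = cur[j - 1] + GAP;
      int best = d; unsigned char db = 0;
      if (u > best) { best = u; db = 1; }
      if (l > best) { best = l; db = 2; }
      cur[j] = best;
      dir[i * (m + 1) + j] = db;
    }
    std::swap(prev, cur);
  }
  int i = n, j = m;
  long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    unsigned char d = dir[i * (m + 1) + j];
    if (i > 0 && j > 0 && d == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (d == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  return cols == 0 ? 1.0 : (double)matches / (double)cols;
}

// [[Rcpp::export]]
double nw_identity_cpp(std::string a, std::string b) {
  return nw_identity_one(a, b);
}

// [[Rcpp::export]]
Rcpp::NumericVector nw_identity_batch(std::string query,
                                      std::vector<std::string> refs) {
  Rcpp::NumericVector out(refs.size());
  for (size_t k = 0; k < refs.size(); ++k) {
    out[k] = nw_identity_one(query, refs[k]);
  }
  return out;
}
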