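#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global Needleman-Wunsch with match +1, mismatch -1, linear gap -2.
// Cell-level ties are broken toward the diagonal (match/mismatch) move, so
// ties fall toward matches; the remaining up-vs-left tie prefers up. The
// traceback yields the number of matching columns and total alignment
// columns, from which percent identity = matches / columns.

static void nwCore(const std::string& a, const std::string& b,
                   int& matches, int& columns, double& score) {
  const int n = (int) a.size(), m = (int) b.size();
  const double GAP = -2.0;
  std::vector<double> H((size_t)(n + 1) * (m + 1));
  std::vector<signed char> T((size_t)(n + 1) * (m + 1));
  const int W = m + 1;
  H[0] = 0.0; T[0] = 0;
  for (int i = 1; i <= n; ++i) { H[(size_t)i * W] = GAP * i; T[(size_t)i * W] = 1; }
  for (int j = 1; j <= m; ++j) { H[j] = GAP * j; T[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = H[(size_t)(i - 1) * W + (j - 1)] +
        (a[i - 1] == b[j - 1] ? 1.0 : -1.0);
      double u = H[(size_t)(i - 1) * W + j] + GAP;
      double l = H[(size_t)i * W + (j - 1)] + GAP;
      double best = d; signed char mv = 0;
      if (u > best) { best = u; mv = 1; }
      if (l > best) { best = l; mv = 2; }
      H[(size_t)i * W + j] = best;
      T[(size_t)i * W + j] = mv;
    }
  }
  score = H[(size_t)n * W + m];
  matches = 0; columns = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char mv = (i == 0) ? 2 : (j == 0) ? 1 : T[(size_t)i * W + j];
    ++columns;
    if (mv == 0) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (mv == 1) { --i; }
    else { --j; }
  }
}

// [[Rcpp::export(name = ".nwIdentity")]]
List nwIdentity(std::string a, std::string b) {
  int matches = 0, columns = 0;
  double score = 0.0;
  nwCore(a, b, matches, columns, score);
  return List::create(_["matches"] = matches, _["columns"] = columns,
                      _["identity"] = columns ? (double) matches / columns : 1.0,
                      _["score"] = score);
}

// [[Rcpp::export(name = ".nwIdentityMany")]]
NumericVector nwIdentityMany(std::string q, CharacterVector refs) {
  NumericVector out(refs.size());
  for (R_xlen_t k = 0; k < refs.size(); ++k) {
    std::string r = as<std::string>(refs[k]);
    int matches = 0, columns = 0;
    double score = 0.0;
    // canonical operand order keeps the identity symmetric
    if (q <= r) nwCore(q, r, matches, columns, score);
    else nwCore(r, q, matches, columns, score);
    out[k] = columns ? (double) matches / columns : 1.0;
  }
  return out;
}
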