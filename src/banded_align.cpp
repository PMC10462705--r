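#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Banded global edit alignment (unit costs: match 0, mismatch 1, indel 1).
// The band is centred on the diagonal rescaled for unequal lengths, so a
// window of width 2*band+1 columns is evaluated per row. Cells outside the
// band are unreachable (infinite cost). Traceback prefers diagonal moves,
// then gaps in `b`, then gaps in `a`, which makes results deterministic.
//
// Returns the edit distance, match count, alignment length, and for every
// position of `a` the character of `b` aligned to it ('-' when `a`'s base
// is unaligned). Characters of `b` inserted relative to `a` are counted in
// the alignment length but not reported per-position; callers doing
// column-majority consensus over `a`'s coordinates do not need them.
// [[Rcpp::export]]
List banded_edit_align(std::string a, std::string b, int band) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0)
    stop("banded_edit_align: empty sequence");
  if (band < 1) band = 1;
  const int ldiff = lb > la ? lb - la : la - lb;
  if (band < ldiff + 1) band = ldiff + 1;
  const int W = 2 * band + 1;
  const int INF = INT_MAX / 4;

  std::vector<int> dp((size_t)(la + 1) * W, INF);
  std::vector<unsigned char> tb((size_t)(la + 1) * W, 0); // 1 diag, 2 up, 3 left

  const double slope = la > 0 ? (double)lb / la : 0.0;
  auto centre = [&](int i) { return (int)std::llround(slope * i); };
  auto at = [&](int i, int j) -> long long {
    int col = j - (centre(i) - band);
    if (j < 0 || j > lb || col < 0 || col >= W) return -1;
    return (long long)i * W + col;
  };

  {
    int off0 = centre(0) - band;
    int hi0 = centre(0) + band; if (hi0 > lb) hi0 = lb;
    for (int j = 0; j <= hi0; ++j) {
      int col = j - off0;
      if (col < 0 || col >= W) continue;
      dp[col] = j;
      tb[col] = j == 0 ? 0 : 3;
    }
  }
  for (int i = 1; i <= la; ++i) {
    const int off = centre(i) - band;
    const int offp = centre(i - 1) - band;
    int lo = off < 0 ? 0 : off;
    int hi = centre(i) + band; if (hi > lb) hi = lb;
    int *row = dp.data() + (size_t)i * W;
    const int *prev = dp.data() + (size_t)(i - 1) * W;
    unsigned char *trow = tb.data() + (size_t)i * W;
    const char ai = a[i - 1];
    for (int j = lo; j <= hi; ++j) {
      const int col = j - off;
      int best = INF;
      unsigned char mv = 0;
      const int cd = j - 1 - offp;
      if (j > 0 && cd >= 0 && cd < W && prev[cd] < INF) {
        int c = prev[cd] + (ai == b[j - 1] ? 0 : 1);
        if (c < best) { best = c; mv = 1; }
      }
      const int cu = j - offp;
      if (cu >= 0 && cu < W && prev[cu] < INF) {
        int c = prev[cu] + 1;
        if (c < best) { best = c; mv = 2; }
      }
      if (j > 0 && col > 0 && row[col - 1] < INF) {
        int c = row[col - 1] + 1;
        if (c < best) { best = c; mv = 3; }
      }
      row[col] = best;
      trow[col] = mv;
    }
  }

  long long kend = at(la, lb);
  if (kend < 0 || dp[kend] >= INF)
    stop("banded_edit_align: end cell outside band");

  std::string b_on_a(la, '-');
  std::vector<std::string> ins(la + 1); // b bases inserted after position i of a
  int i = la, j = lb, matches = 0, alnlen = 0;
  while (i > 0 || j > 0) {
    unsigned char mv = tb[at(i, j)];
    if (mv == 1) {
      b_on_a[i - 1] = b[j - 1];
      if (a[i - 1] == b[j - 1]) ++matches;
      ++alnlen; --i; --j;
    } else if (mv == 2) {
      ++alnlen; --i;
    } else if (mv == 3) {
      ins[i].insert(ins[i].begin(), b[j - 1]); // traceback is right-to-left
      ++alnlen; --j;
    } else {
      stop("banded_edit_align: traceback failed");
    }
  }

  return List::create(_["distance"] = dp[kend], _["matches"] = matches,
                      _["alnlen"] = alnlen, _["aligned"] = b_on_a,
                      _["ins_after"] = wrap(ins));
}
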