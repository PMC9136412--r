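#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Ends-free (overlap) global alignment with affine gaps.
// Scoring: match +1, mismatch 0, gap of length L costs open + L * extend.
// Leading and trailing gaps in either sequence are free and excluded from
// the identity denominator. Ties in the traceback are broken by preferring
// diagonal (match state), then up (gap in b, consuming a), then left.
// Endpoint ties are broken by preferring (n, m), then the last column
// bottom-up, then the last row right-to-left.

static const double NEG = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (up / gap in b), 2 = Y (left / gap
// in a), 3 = start (boundary)

// [[Rcpp::export]]
List align_overlap_affine(std::string a, std::string b,
                          double match = 1.0, double mismatch = 0.0,
                          double gap_open = 10.0, double gap_extend = 0.5) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG), X((n + 1) * w, NEG),
      Y((n + 1) * w, NEG);
  std::vector<signed char> tM((n + 1) * w, 3), tX((n + 1) * w, 3),
      tY((n + 1) * w, 3);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * w] = 0.0;   // free leading gap in b
  for (int j = 1; j <= m; ++j) Y[j] = 0.0;       // free leading gap in a
  const double go = gap_open + gap_extend;       // cost of opening (len 1)

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * w + j, d = (i - 1) * w + (j - 1),
                u = (i - 1) * w + j, l = i * w + (j - 1);
      // M: prefer M > X > Y among predecessors
      double best = M[d]; signed char tb = 0;
      if (X[d] > best) { best = X[d]; tb = 1; }
      if (Y[d] > best) { best = Y[d]; tb = 2; }
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      M[c] = best + s; tM[c] = (best == NEG) ? 3 : tb;
      // X: consume a[i-1] against a gap
      best = M[u] - go; tb = 0;
      if (X[u] - gap_extend > best) { best = X[u] - gap_extend; tb = 1; }
      if (Y[u] - go > best) { best = Y[u] - go; tb = 2; }
      X[c] = best; tX[c] = tb;
      // Y: consume b[j-1] against a gap (uniform codes 0=M, 1=X, 2=Y)
      best = M[l] - go; tb = 0;
      if (X[l] - go > best) { best = X[l] - go; tb = 1; }
      if (Y[l] - gap_extend > best) { best = Y[l] - gap_extend; tb = 2; }
      Y[c] = best; tY[c] = tb;
    }
  }

  // endpoint selection
  double bestScore = NEG; int bi = -1, bj = -1; signed char bs = 0;
  auto consider = [&](int i, int j) {
    const int c = i * w + j;
    const double vals[3] = {M[c], X[c], Y[c]};
    for (int s = 0; s < 3; ++s)
      if (vals[s] > bestScore) { bestScore = vals[s]; bi = i; bj = j; bs = s; }
  };
  consider(n, m);
  for (int i = n - 1; i >= 0; --i) consider(i, m);
  for (int j = m - 1; j >= 0; --j) consider(n, j);

  // traceback
  long matches = 0, columns = 0;
  int i = bi, j = bj; signed char s = bs;
  while (i > 0 && j > 0) {
    const int c = i * w + j;
    if (s == 0) {
      ++columns; if (a[i - 1] == b[j - 1]) ++matches;
      signed char t = tM[c]; --i; --j;
      if (t == 3) break;
      s = t;
    } else if (s == 1) {
      ++columns;
      s = tX[c]; --i;
    } else {
      ++columns;
      s = tY[c]; --j;
    }
  }
  double identity = (columns > 0) ? 100.0 * matches / columns : 0.0;
  return List::create(_["score"] = bestScore, _["matches"] = (double)matches,
                      _["columns"] = (double)columns,
                      _["identity"] = identity);
}
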