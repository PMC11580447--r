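#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). Gap of length L costs
// open + (L - 1) * extend (penalties are negative). Traceback tie-break is
// fixed: diagonal (substitution) > up (gap in b) > left (gap in a), applied
// both to state choice and within-state predecessor choice.

static const double NINF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
              double gapOpen, double gapExtend) {
  const int n = a.size(), m = b.size();
  NumericMatrix Mm(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  std::fill(Mm.begin(), Mm.end(), NINF);
  std::fill(Ix.begin(), Ix.end(), NINF);
  std::fill(Iy.begin(), Iy.end(), NINF);
  Mm(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) Ix(i, 0) = gapOpen + (i - 1) * gapExtend;
  for (int j = 1; j <= m; ++j) Iy(0, j) = gapOpen + (j - 1) * gapExtend;

  // state codes 0 = M (diagonal), 1 = Ix (up), 2 = Iy (left)
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);
  auto pick = [](double vm, double vx, double vy, int &ptr) {
    double best = vm; ptr = 0;
    if (vx > best) { best = vx; ptr = 1; }
    if (vy > best) { best = vy; ptr = 2; }
    return best;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int ptr;
      double d = pick(Mm(i - 1, j - 1), Ix(i - 1, j - 1), Iy(i - 1, j - 1),
                      ptr);
      Mm(i, j) = sub(a[i - 1], b[j - 1]) + d;
      pM(i, j) = ptr;
      double x = pick(Mm(i - 1, j) + gapOpen, Ix(i - 1, j) + gapExtend,
                      Iy(i - 1, j) + gapOpen, ptr);
      Ix(i, j) = x; pX(i, j) = ptr;
      double y = pick(Mm(i, j - 1) + gapOpen, Ix(i, j - 1) + gapOpen,
                      Iy(i, j - 1) + gapExtend, ptr);
      Iy(i, j) = y; pY(i, j) = ptr;
    }
  }

  int cur;
  double score = pick(Mm(n, m), Ix(n, m), Iy(n, m), cur);
  if (n == 0 || m == 0) { // pure gap alignment
    score = (n + m == 0) ? 0.0 : gapOpen + (n + m - 1) * gapExtend;
    cur = n > 0 ? 1 : 2;
  }

  std::vector<int> ai, bi; // 1-based positions, 0 for gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) cur = 2; else if (j == 0) cur = 1; // only gaps remain
    int prev;
    if (cur == 0) { ai.push_back(i); bi.push_back(j); prev = pM(i, j); --i; --j; }
    else if (cur == 1) { ai.push_back(i); bi.push_back(0); prev = pX(i, j); --i; }
    else { ai.push_back(0); bi.push_back(j); prev = pY(i, j); --j; }
    cur = prev;
  }
  const int L = ai.size();
  IntegerVector A(L), B(L);
  for (int c = 0; c < L; ++c) { A[c] = ai[L - 1 - c]; B[c] = bi[L - 1 - c]; }
  return List::create(_["score"] = score, _["a"] = A, _["b"] = B);
}
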