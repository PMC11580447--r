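#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Profile-HMM DP kernels. All scores are log2-odds against the background;
// emission matrices arrive as log2(em/bg) with X residues encoded as -1
// (odds 1, i.e. contribution 0). Transition matrix rows are nodes 0..M with
// columns MM MI MD IM II DM DD in log2 probability; row 0 is the begin node
// and in row M the MM/IM/DM slots are the exits to the end state.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  double m, d;
  if (a >= b) { m = a; d = b - a; } else { m = b; d = a - b; }
  if (d < -40.0 || m == NEG_INF) return m; // 2^-40 below double rounding
  return m + std::log1p(std::exp2(d)) / M_LN2;
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

enum { MM = 0, MI, MD, IM, II, DM, DD };

// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(NumericMatrix lmat, NumericMatrix lins,
                    NumericMatrix ltr, IntegerVector seq) {
  const int M = lmat.nrow();
  const int L = seq.size();
  NumericMatrix fM(M + 1, L + 1), fI(M + 1, L + 1), fD(M + 1, L + 1);
  std::fill(fM.begin(), fM.end(), NEG_INF);
  std::fill(fI.begin(), fI.end(), NEG_INF);
  std::fill(fD.begin(), fD.end(), NEG_INF);
  fM(0, 0) = 0.0; // begin state, nothing emitted

  for (int i = 0; i <= L; ++i) {
    int s = i >= 1 ? seq[i - 1] : -2;
    for (int k = 0; k <= M; ++k) {
      if (k >= 1) {
        if (i >= 1) {
          double em = s >= 0 ? lmat(k - 1, s) : 0.0;
          fM(k, i) = em + lse3(fM(k - 1, i - 1) + ltr(k - 1, MM),
                               fI(k - 1, i - 1) + ltr(k - 1, IM),
                               fD(k - 1, i - 1) + ltr(k - 1, DM));
        }
        fD(k, i) = lse2(fM(k - 1, i) + ltr(k - 1, MD),
                        fD(k - 1, i) + ltr(k - 1, DD));
      }
      if (i >= 1) {
        double em = s >= 0 ? lins(k, s) : 0.0;
        fI(k, i) = em + lse2(fM(k, i - 1) + ltr(k, MI),
                             fI(k, i - 1) + ltr(k, II));
      }
    }
  }
  return lse3(fM(M, L) + ltr(M, MM),
              fI(M, L) + ltr(M, IM),
              fD(M, L) + ltr(M, DM));
}

// Viterbi with fixed tie-break priority M < D < I when predecessor scores
// are exactly equal.
// [[Rcpp::export(name = ".phmm_viterbi")]]
List phmm_viterbi(NumericMatrix lmat, NumericMatrix lins,
                  NumericMatrix ltr, IntegerVector seq) {
  const int M = lmat.nrow();
  const int L = seq.size();
  NumericMatrix vM(M + 1, L + 1), vI(M + 1, L + 1), vD(M + 1, L + 1);
  IntegerMatrix pM(M + 1, L + 1), pI(M + 1, L + 1), pD(M + 1, L + 1);
  std::fill(vM.begin(), vM.end(), NEG_INF);
  std::fill(vI.begin(), vI.end(), NEG_INF);
  std::fill(vD.begin(), vD.end(), NEG_INF);
  vM(0, 0) = 0.0;

  // predecessor codes: 0 = M, 1 = D, 2 = I (priority order on ties)
  auto best3 = [](double m, double d, double i, int &ptr) {
    double b = m; ptr = 0;
    if (d > b) { b = d; ptr = 1; }
    if (i > b) { b = i; ptr = 2; }
    return b;
  };

  for (int i = 0; i <= L; ++i) {
    int s = i >= 1 ? seq[i - 1] : -2;
    for (int k = 0; k <= M; ++k) {
      int ptr;
      if (k >= 1) {
        if (i >= 1) {
          double em = s >= 0 ? lmat(k - 1, s) : 0.0;
          double b = best3(vM(k - 1, i - 1) + ltr(k - 1, MM),
                           vD(k - 1, i - 1) + ltr(k - 1, DM),
                           vI(k - 1, i - 1) + ltr(k - 1, IM), ptr);
          vM(k, i) = em + b; pM(k, i) = ptr;
        }
        double b = best3(vM(k - 1, i) + ltr(k - 1, MD),
                         vD(k - 1, i) + ltr(k - 1, DD), NEG_INF, ptr);
        vD(k, i) = b; pD(k, i) = ptr;
      }
      if (i >= 1) {
        double em = s >= 0 ? lins(k, s) : 0.0;
        double b = best3(vM(k, i - 1) + ltr(k, MI), NEG_INF,
                         vI(k, i - 1) + ltr(k, II), ptr);
        vI(k, i) = em + b; pI(k, i) = ptr;
      }
    }
  }

  int cur;
  double score = best3(vM(M, L) + ltr(M, MM),
                       vD(M, L) + ltr(M, DM),
                       vI(M, L) + ltr(M, IM), cur);

  // trace back; states recorded as (type, node, seqpos) with type
  // 0 = M, 1 = D, 2 = I and seqpos the 1-based emitted position (0 if none)
  std::vector<int> types, nodes, poss;
  int k = M, i = L;
  while (!(k == 0 && i == 0)) {
    types.push_back(cur);
    int prev;
    if (cur == 0) { // match state M_k emitted residue i
      nodes.push_back(k); poss.push_back(i);
      prev = pM(k, i); --k; --i;
    } else if (cur == 1) { // delete
      nodes.push_back(k); poss.push_back(0);
      prev = pD(k, i); --k;
    } else { // insert I_k emitted residue i
      nodes.push_back(k); poss.push_back(i);
      prev = pI(k, i); --i;
    }
    cur = prev;
  }
  int n = types.size();
  IntegerMatrix path(n, 3);
  IntegerVector matchTrace(M);
  for (int r = 0; r < n; ++r) {
    int rr = n - 1 - r;
    path(r, 0) = types[rr]; path(r, 1) = nodes[rr]; path(r, 2) = poss[rr];
    if (types[rr] == 0) matchTrace[nodes[rr] - 1] = poss[rr];
  }
  return List::create(_["score"] = score, _["path"] = path,
                      _["matchTrace"] = matchTrace);
}
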