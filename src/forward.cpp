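// Log-space forward algorithm for the glocal profile HMM used in insertion
// dating.  The full profile must be traversed (M/I/D lattice); any prefix and
// suffix of the sequence outside the aligned region is emitted by the
// background null model and therefore contributes zero log-odds.  Scores are
// natural-log odds (nats) against an iid background.
//
// Transition scheme (documented in build_profile()):
//   B  -> M1 0.90 | I0 0.05 | D1 0.05
//   Mj -> Mj+1 0.90 | Ij 0.05 | Dj+1 0.05   (j < L)
//   ML -> E 0.95 | IL 0.05
//   Ij -> Mj+1 0.70 | Ij 0.30               (IL -> E 0.70 | IL 0.30)
//   Dj -> Mj+1 0.70 | Dj+1 0.30             (DL -> E 1.00)
// Insert states emit the background distribution (log-odds 0).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == -INFINITY) return b;
  if (b == -INFINITY) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) { return lse2(lse2(a, b), c); }

// [[Rcpp::export(name = ".forward_score_cpp")]]
double forward_score_cpp(NumericMatrix match_log_odds, IntegerVector seq,
                         NumericVector trans) {
  const int L = match_log_odds.ncol();
  const int n = seq.size();
  const double NEGINF = -INFINITY;
  const double lBM = std::log(trans["BM"]), lBI = std::log(trans["BI"]),
    lBD = std::log(trans["BD"]), lMM = std::log(trans["MM"]),
    lMI = std::log(trans["MI"]), lMD = std::log(trans["MD"]),
    lIM = std::log(trans["IM"]), lII = std::log(trans["II"]),
    lDM = std::log(trans["DM"]), lDD = std::log(trans["DD"]),
    lME = std::log(trans["ME"]), lIE = std::log(trans["IE"]),
    lDE = std::log(trans["DE"]);

  // fM[j][i], fI[j][i], fD[j][i]: forward log-odds having consumed i aligned
  // residues and reached state (X, j).  Entry is free at every residue index
  // (the skipped prefix scores zero against the null).
  std::vector<std::vector<double>> fM(L + 1, std::vector<double>(n + 1, NEGINF));
  std::vector<std::vector<double>> fD(L + 1, std::vector<double>(n + 1, NEGINF));
  std::vector<std::vector<double>> fI(L + 1, std::vector<double>(n + 1, NEGINF));
  // fI[0] is the I0 state reached directly from B.

  auto em = [&](int j, int i) { // log-odds of match column j emitting residue i (1-based)
    int b = seq[i - 1];
    if (b < 0) return 0.0; // N scores as background
    return match_log_odds(b, j - 1);
  };

  for (int i = 1; i <= n; ++i)
    fI[0][i] = lse2(lBI, (i >= 2 ? fI[0][i - 1] + lII : NEGINF));

  for (int i = 0; i <= n; ++i) fD[1][i] = lBD;

  for (int j = 1; j <= L; ++j) {
    for (int i = 1; i <= n; ++i) {
      double acc;
      if (j == 1) {
        acc = lse2(lBM, fI[0][i - 1] + lIM);
      } else {
        acc = lse3(fM[j - 1][i - 1] + lMM,
                   fI[j - 1][i - 1] + lIM,
                   fD[j - 1][i - 1] + lDM);
      }
      fM[j][i] = em(j, i) + acc;
    }
    for (int i = 1; i <= n; ++i)
      fI[j][i] = lse2(fM[j][i - 1] + lMI, fI[j][i - 1] + lII);
    if (j + 1 <= L) {
      for (int i = 0; i <= n; ++i)
        fD[j + 1][i] = lse2(fM[j][i] + lMD, fD[j][i] + lDD);
    }
  }

  double total = NEGINF;
  for (int i = 0; i <= n; ++i) {
    if (i >= 1) total = lse2(total, fM[L][i] + lME);
    if (i >= 1) total = lse2(total, fI[L][i] + lIE);
    total = lse2(total, fD[L][i] + lDE);
  }
  return total;
}
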