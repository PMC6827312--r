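#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Profile-HMM scoring in odds-ratio space with per-row rescaling.
//
// The model has M match states with emission probabilities me (M x 20),
// insert states emitting the background composition (so insert emission
// odds are 1), and delete states. tr is an M x 7 matrix of transition
// probabilities out of position k (1-based rows):
//   col 0 MM: M_k -> M_{k+1}   col 1 MI: M_k -> I_k   col 2 MD: M_k -> D_{k+1}
//   col 3 IM: I_k -> M_{k+1}   col 4 II: I_k -> I_k
//   col 5 DM: D_k -> M_{k+1}   col 6 DD: D_k -> D_{k+1}
// Local alignment uses uniform entry into any match state with probability
// 2 / (M (M + 1)) and free exit from any match state; unaligned flanking
// residues are emitted by the null model and cancel in the odds ratio.
// x holds 0-based residue indices; -1 marks an ambiguous residue whose
// emission odds are taken as 1.

static double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = std::max(a, b);
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// [[Rcpp::export]]
double hmm_forward(IntegerVector x, NumericMatrix me, NumericVector bg,
                   NumericMatrix tr) {
  const int L = x.size(), M = me.nrow();
  const double entry = 2.0 / (double(M) * (M + 1.0));
  std::vector<double> Mprev(M + 1, 0.0), Iprev(M + 1, 0.0), Dprev(M + 1, 0.0);
  std::vector<double> Mcur(M + 1), Icur(M + 1), Dcur(M + 1);
  double logscale = 0.0, total = R_NegInf;
  for (int i = 1; i <= L; ++i) {
    const int a = x[i - 1];
    Mcur[0] = Icur[0] = Dcur[0] = 0.0;
    double rowsum = 0.0, rowmax = 0.0;
    for (int k = 1; k <= M; ++k) {
      const double er = (a >= 0) ? me(k - 1, a) / bg[a] : 1.0;
      double in = entry;
      if (k > 1)
        in += Mprev[k - 1] * tr(k - 2, 0) + Iprev[k - 1] * tr(k - 2, 3) +
              Dprev[k - 1] * tr(k - 2, 5);
      Mcur[k] = er * in;
      Icur[k] = Mprev[k] * tr(k - 1, 1) + Iprev[k] * tr(k - 1, 4);
      Dcur[k] = (k > 1)
                    ? Mcur[k - 1] * tr(k - 2, 2) + Dcur[k - 1] * tr(k - 2, 6)
                    : 0.0;
      rowsum += Mcur[k];
      rowmax = std::max(rowmax, std::max(Mcur[k], std::max(Icur[k], Dcur[k])));
    }
    if (rowsum > 0.0)
      total = logsumexp2(total, std::log2(rowsum) + logscale);
    if (rowmax > 1e100 || (rowmax > 0.0 && rowmax < 1e-100)) {
      const double inv = 1.0 / rowmax;
      for (int k = 1; k <= M; ++k) {
        Mcur[k] *= inv; Icur[k] *= inv; Dcur[k] *= inv;
      }
      logscale += std::log2(rowmax);
    }
    std::swap(Mprev, Mcur);
    std::swap(Iprev, Icur);
    std::swap(Dprev, Dcur);
  }
  return total;
}

// [[Rcpp::export]]
double hmm_viterbi(IntegerVector x, NumericMatrix me, NumericVector bg,
                   NumericMatrix tr) {
  const int L = x.size(), M = me.nrow();
  const double entry = 2.0 / (double(M) * (M + 1.0));
  std::vector<double> Mprev(M + 1, 0.0), Iprev(M + 1, 0.0), Dprev(M + 1, 0.0);
  std::vector<double> Mcur(M + 1), Icur(M + 1), Dcur(M + 1);
  double logscale = 0.0, best = R_NegInf;
  for (int i = 1; i <= L; ++i) {
    const int a = x[i - 1];
    Mcur[0] = Icur[0] = Dcur[0] = 0.0;
    double rowmax = 0.0;
    for (int k = 1; k <= M; ++k) {
      const double er = (a >= 0) ? me(k - 1, a) / bg[a] : 1.0;
      double in = entry;
      if (k > 1) {
        in = std::max(in, Mprev[k - 1] * tr(k - 2, 0));
        in = std::max(in, Iprev[k - 1] * tr(k - 2, 3));
        in = std::max(in, Dprev[k - 1] * tr(k - 2, 5));
      }
      Mcur[k] = er * in;
      Icur[k] = std::max(Mprev[k] * tr(k - 1, 1), Iprev[k] * tr(k - 1, 4));
      Dcur[k] = (k > 1) ? std::max(Mcur[k - 1] * tr(k - 2, 2),
                                   Dcur[k - 1] * tr(k - 2, 6))
                        : 0.0;
      if (Mcur[k] > 0.0)
        best = std::max(best, std::log2(Mcur[k]) + logscale);
      rowmax = std::max(rowmax, std::max(Mcur[k], std::max(Icur[k], Dcur[k])));
    }
    if (rowmax > 1e100 || (rowmax > 0.0 && rowmax < 1e-100)) {
      const double inv = 1.0 / rowmax;
      for (int k = 1; k <= M; ++k) {
        Mcur[k] *= inv; Icur[k] *= inv; Dcur[k] *= inv;
      }
      logscale += std::log2(rowmax);
    }
    std::swap(Mprev, Mcur);
    std::swap(Iprev, Icur);
    std::swap(Dprev, Dcur);
  }
  return best;
}
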