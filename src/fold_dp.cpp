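#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Maximum base-pairing dynamic program with nearest-neighbour stack bonuses.
// P[i][j]: best score of [i..j] given (i,j) paired; M[i][j]: best score of
// [i..j]. Watson-Crick + GU wobble pairs; hairpin loops of >= min_loop
// unpaired bases. Score = pair_bonus per pair + stack_bonus per directly
// stacked pair; reported energy is the negated score.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

static double fold_one(const std::string& s, double pair_bonus,
                       double stack_bonus, int min_loop) {
  const int n = (int) s.size();
  if (n < 2) return 0.0;
  const double NEG = -1e18;
  std::vector<std::vector<double>> M(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> P(n, std::vector<double>(n, NEG));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (can_pair(s[i], s[j])) {
        double inner = (i + 1 <= j - 1) ? M[i + 1][j - 1] : 0.0;
        double stacked = (P[i + 1][j - 1] > NEG / 2)
                           ? P[i + 1][j - 1] + stack_bonus : NEG;
        P[i][j] = pair_bonus + std::max(inner, stacked);
      }
      double best = std::max(M[i + 1][j], M[i][j - 1]);
      for (int k = i; k < j; ++k) {
        if (P[k][j] > NEG / 2) {
          double left = (k > i) ? M[i][k - 1] : 0.0;
          best = std::max(best, left + P[k][j]);
        }
      }
      M[i][j] = best;
    }
  }
  return -M[0][n - 1];
}

// [[Rcpp::export(name = ".fold_energy_cpp")]]
NumericVector fold_energy_cpp(CharacterVector seqs, double pair_bonus,
                              double stack_bonus, int min_loop) {
  NumericVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = fold_one(s, pair_bonus, stack_bonus, min_loop);
  }
  return out;
}
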