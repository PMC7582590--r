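#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimum-energy pseudoknot-free secondary structure by Nussinov-style
// dynamic programming. Bases are encoded 0=A, 1=C, 2=G, 3=U/T. Pair
// energies (negative = stabilizing) are supplied for GC, AU and GU pairs;
// hairpin loops must enclose at least min_loop unpaired bases.
static inline double pair_energy(int a, int b, double e_gc, double e_au,
                                 double e_gu) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return e_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return e_au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return e_gu;
  return 0.0; // non-canonical: never beneficial, never chosen
}

// [[Rcpp::export(name = ".nussinov_mfe")]]
double nussinov_mfe(IntegerVector seq, double e_gc, double e_au,
                    double e_gu, int min_loop) {
  int n = seq.size();
  if (n < 2) return 0.0;
  std::vector<double> E((size_t)n * n, 0.0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = E[(size_t)(i + 1) * n + j];          // i unpaired
      double v = E[(size_t)i * n + (j - 1)];             // j unpaired
      if (v < best) best = v;
      double pe = pair_energy(seq[i], seq[j], e_gc, e_au, e_gu);
      if (pe < 0.0) {                                    // pair (i, j)
        double inner = (j - 1 >= i + 1) ? E[(size_t)(i + 1) * n + (j - 1)]
                                        : 0.0;
        v = pe + inner;
        if (v < best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {                  // bifurcation
        v = E[(size_t)i * n + k] + E[(size_t)(k + 1) * n + j];
        if (v < best) best = v;
      }
      E[(size_t)i * n + j] = best;
    }
  }
  return E[(size_t)(n - 1)];
}
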