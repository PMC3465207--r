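// Exact cost deltas for the merge operator, evaluated in batch over many
// candidate pairs. For a pair (X, Y) -> M the delta accounts for:
//   - the inventory shrinking by one symbol (every production is re-costed
//     with log2(|Sigma| - 1)),
//   - productions that become identical after relabelling and collapse
//     (their encoded symbols leave the grammar cost; per-LHS expansion
//     counts |P(.)| shrink),
//   - the merged symbol's expansion count |P(M)| and its total number of
//     derivation-step usages u(X) + u(Y).
// The derivation cost is Sigma_s u(s) * log2(|P(s)|), so only groups whose
// production set changes contribute to the delta.
//
// Symbol coding matches parser.cpp: nonterminals 1..n_nt, terminals above.

#include <Rcpp.h>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double l2(double c) { return c > 0 ? std::log2(c) : 0.0; }

// [[Rcpp::export]]
NumericVector cpp_merge_deltas(int n_nt, IntegerVector r_lhs, List r_rhs,
                               IntegerMatrix pairs, NumericVector u,
                               int n_term, double f) {
  int R = (int)r_lhs.size();
  std::vector<std::vector<int>> rhs(R);
  std::vector<int> lhs = as<std::vector<int>>(r_lhs);
  long T = 0;
  std::vector<int> pcount(n_nt + 1, 0);
  std::vector<std::vector<int>> by_lhs(n_nt + 1), touch(n_nt + 1);
  for (int r = 0; r < R; ++r) {
    rhs[r] = as<std::vector<int>>(r_rhs[r]);
    T += 1 + (long)rhs[r].size();
    pcount[lhs[r]]++;
    by_lhs[lhs[r]].push_back(r);
    std::set<int> syms;
    syms.insert(lhs[r]);
    for (int s : rhs[r]) if (s <= n_nt) syms.insert(s);
    for (int s : syms) touch[s].push_back(r);
  }
  double sigma = (double)(n_nt + n_term);
  if (sigma - 1 < 2) stop("invalid inventory: merge would leave |Sigma| < 2");
  double log2sig = std::log2(sigma), log2sigm = std::log2(sigma - 1);

  int m = pairs.nrow();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    int X = pairs(k, 0), Y = pairs(k, 1);
    if (X < 1 || X > n_nt || Y < 1 || Y > n_nt || X == Y)
      stop("stale candidate: bad merge pair");
    long removed = 0;
    double dCD = 0.0;
    auto process = [&](const std::vector<int>& idx, double uSum,
                       double oldBits) {
      std::set<std::vector<int>> uniq;
      for (int r : idx) {
        std::vector<int> key = rhs[r];
        for (int& s : key) if (s == Y) s = X;
        if (!uniq.insert(key).second) removed += 1 + (long)key.size();
      }
      dCD += uSum * l2((double)uniq.size()) - oldBits;
    };
    // merged group: all rules with lhs X or Y
    std::vector<int> mg(by_lhs[X]);
    mg.insert(mg.end(), by_lhs[Y].begin(), by_lhs[Y].end());
    if (!mg.empty())
      process(mg, u[X - 1] + u[Y - 1],
              u[X - 1] * l2((double)pcount[X]) +
                  u[Y - 1] * l2((double)pcount[Y]));
    // other groups containing X or Y on a right-hand side
    std::set<int> gs;
    for (int s : {X, Y})
      for (int r : touch[s])
        if (lhs[r] != X && lhs[r] != Y) gs.insert(lhs[r]);
    for (int L : gs)
      process(by_lhs[L], u[L - 1], u[L - 1] * l2((double)pcount[L]));

    double dCG = (double)(T - removed) * log2sigm - (double)T * log2sig;
    out[k] = f * dCG + (1 - f) * dCD;
  }
  return out;
}
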