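// Probabilistic chart parser for CFGs with arbitrary-length right-hand
// sides (no binarisation). Dynamic program over spans; for every rule a
// backward tiling DP matches its RHS against the span. Ties between
// maximum-probability parses are broken deterministically: lowest
// production creation order at the topmost decision, then recursively on
// children left to right, earlier split points preferred. Rules must be
// passed in creation order.
//
// Symbol coding: nonterminals are 1..n_nt, terminals are n_nt+1.. .
// Spans are 0-based half-open over the token sequence.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

namespace {

struct Parser {
  int n_nt = 0, n = 0;
  std::vector<int> lhs;                  // 1-based NT id per rule
  std::vector<std::vector<int>> rhs;     // symbol ids per rule
  std::vector<double> logp;
  std::vector<int> sent;                 // terminal ids
  std::vector<double> best;              // best[(A,i,j)]
  std::vector<int> out_rule, out_i, out_j;
  long depth = 0;

  double& B(int A, int i, int j) {
    return best[(size_t)((A - 1) * (n + 1) + i) * (n + 1) + j];
  }

  // b[d][p-i] = best score of matching rhs[d..L) of rule r to tokens p..j.
  void backward(int r, int i, int j, std::vector<std::vector<double>>& b) {
    const std::vector<int>& R = rhs[r];
    int L = (int)R.size(), w = j - i + 1;
    b.assign(L + 1, std::vector<double>(w, NEG_INF));
    b[L][j - i] = 0.0;
    for (int d = L - 1; d >= 0; --d) {
      int sym = R[d];
      if (sym > n_nt) {  // terminal: consumes exactly token p
        for (int p = i; p < j; ++p) {
          if (sent[p] == sym && b[d + 1][p + 1 - i] > NEG_INF)
            b[d][p - i] = b[d + 1][p + 1 - i];
        }
      } else {
        for (int p = i; p <= j; ++p) {
          double bv = NEG_INF;
          for (int q = p + 1; q <= j; ++q) {
            double child = B(sym, p, q), rest = b[d + 1][q - i];
            if (child > NEG_INF && rest > NEG_INF) {
              double v = child + rest;
              if (v > bv) bv = v;
            }
          }
          b[d][p - i] = bv;
        }
      }
    }
  }

  void fill() {
    best.assign((size_t)n_nt * (n + 1) * (n + 1), NEG_INF);
    std::vector<std::vector<double>> b;
    int R = (int)rhs.size();
    for (int len = 1; len <= n; ++len) {
      for (int i = 0; i + len <= n; ++i) {
        int j = i + len;
        for (int r = 0; r < R; ++r) {
          int L = (int)rhs[r].size();
          if (L > len || logp[r] == NEG_INF) continue;
          double s = NEG_INF;
          if (L == 1 && rhs[r][0] > n_nt) {
            if (len == 1 && sent[i] == rhs[r][0]) s = logp[r];
          } else if (L == 1) {
            double child = B(rhs[r][0], i, j);
            if (child > NEG_INF) s = logp[r] + (child + 0.0);
          } else {
            backward(r, i, j, b);
            if (b[0][0] > NEG_INF) s = logp[r] + b[0][0];
          }
          double& cur = B(lhs[r], i, j);
          if (s > cur) cur = s;
        }
        // relax unit nonterminal rules (same-span dependencies) to fixpoint
        bool improved = true;
        int guard = 0;
        while (improved && guard++ <= n_nt + 2) {
          improved = false;
          for (int r = 0; r < R; ++r) {
            if (rhs[r].size() != 1 || rhs[r][0] > n_nt) continue;
            if (logp[r] == NEG_INF) continue;
            double child = B(rhs[r][0], i, j);
            if (child == NEG_INF) continue;
            double s = logp[r] + (child + 0.0);
            double& cur = B(lhs[r], i, j);
            if (s > cur) { cur = s; improved = true; }
          }
        }
      }
    }
  }

  void extract(int A, int i, int j) {
    if (++depth > 200000)
      stop("parse extraction depth exceeded (cyclic grammar?)");
    double target = B(A, i, j);
    if (target == NEG_INF) stop("internal parser error: extracting no-parse");
    std::vector<std::vector<double>> b;
    int R = (int)rhs.size();
    for (int r = 0; r < R; ++r) {
      if (lhs[r] != A) continue;
      int L = (int)rhs[r].size();
      if (L > j - i || logp[r] == NEG_INF) continue;
      backward(r, i, j, b);
      if (b[0][0] == NEG_INF || logp[r] + b[0][0] != target) continue;
      out_rule.push_back(r);
      out_i.push_back(i);
      out_j.push_back(j);
      int p = i;
      for (int d = 0; d < L; ++d) {
        int sym = rhs[r][d];
        if (sym > n_nt) { ++p; continue; }
        bool found = false;
        for (int q = p + 1; q <= j && !found; ++q) {
          double child = B(sym, p, q), rest = b[d + 1][q - i];
          if (child > NEG_INF && rest > NEG_INF &&
              child + rest == b[d][p - i]) {
            extract(sym, p, q);
            p = q;
            found = true;
          }
        }
        if (!found) stop("internal parser error: split not found");
      }
      --depth;
      return;
    }
    stop("internal parser error: no rule achieves chart value");
  }
};

void load_rules(Parser& P, int n_nt, const IntegerVector& r_lhs,
                const List& r_rhs, const NumericVector& r_logp) {
  P.n_nt = n_nt;
  P.lhs = as<std::vector<int>>(r_lhs);
  P.rhs.clear();
  P.rhs.reserve(r_rhs.size());
  for (R_xlen_t k = 0; k < r_rhs.size(); ++k)
    P.rhs.push_back(as<std::vector<int>>(r_rhs[k]));
  P.logp = as<std::vector<double>>(r_logp);
}

List run_one(Parser& P, int start) {
  P.fill();
  double lp = P.B(start, 0, P.n);
  if (lp == NEG_INF) {
    return List::create(_["ok"] = false);
  }
  P.out_rule.clear(); P.out_i.clear(); P.out_j.clear();
  P.depth = 0;
  P.extract(start, 0, P.n);
  IntegerVector rule(P.out_rule.begin(), P.out_rule.end());
  return List::create(
    _["ok"] = true,
    _["logprob"] = lp,
    _["rule"] = rule + 1,  // 1-based rule indices, preorder
    _["i"] = IntegerVector(P.out_i.begin(), P.out_i.end()),
    _["j"] = IntegerVector(P.out_j.begin(), P.out_j.end()));
}

}  // namespace

// [[Rcpp::export]]
List cpp_parse(int n_nt, IntegerVector r_lhs, List r_rhs,
               NumericVector r_logp, int start, IntegerVector sent) {
  Parser P;
  load_rules(P, n_nt, r_lhs, r_rhs, r_logp);
  P.sent = as<std::vector<int>>(sent);
  P.n = (int)P.sent.size();
  return run_one(P, start);
}

// [[Rcpp::export]]
List cpp_parse_batch(int n_nt, IntegerVector r_lhs, List r_rhs,
                     NumericVector r_logp, int start, List sentences) {
  Parser P;
  load_rules(P, n_nt, r_lhs, r_rhs, r_logp);
  List out(sentences.size());
  for (R_xlen_t k = 0; k < sentences.size(); ++k) {
    IntegerVector sent = sentences[k];
    P.sent = as<std::vector<int>>(sent);
    P.n = (int)P.sent.size();
    out[k] = run_one(P, start);
  }
  return out;
}
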