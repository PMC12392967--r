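#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap alignment with deterministic traceback.
//
// States: H (best ending in M/X), E (ending in D, gap in query / consumes ref),
// F (ending in I, gap in ref / consumes query). Gap of length L costs
// gap_open + L * gap_extend. Tie preference during traceback: M/X > D > I,
// giving a single reproducible path.
//
// mode "local": Smith-Waterman (0-floor); start cell = highest score, ties
// resolved toward smallest query index then smallest ref index.
// mode "overlap": global with free end gaps on both sequences; the score is
// the maximum over the last row and last column, ties preferring the
// bottom-right-most cell on the last row scan order (see below), and the
// leading free gaps are reported as ref_start/query_start offsets, not ops.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct OpRun { char op; int len; };

static void push_op(std::vector<OpRun> &ops, char op) {
  if (!ops.empty() && ops.back().op == op) ops.back().len++;
  else ops.push_back({op, 1});
}

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string query, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     std::string mode) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  const bool local = (mode == "local");

  // (n+1) x (m+1) matrices, row-major
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG_INF);
  std::vector<double> F((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  // boundary: H = 0 everywhere on row 0 / col 0 (local floor or free end gaps)
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      double e = std::max(H[at(i, j - 1)] - gap_open, E[at(i, j - 1)]) - gap_extend;
      double f = std::max(H[at(i - 1, j)] - gap_open, F[at(i - 1, j)]) - gap_extend;
      double s = (query[i - 1] == ref[j - 1]) ? match : -mismatch;
      double d = H[at(i - 1, j - 1)] + s;
      double h = d;
      if (e > h) h = e;
      if (f > h) h = f;
      if (local && h < 0.0) h = 0.0;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
    }
  }

  // locate alignment end
  int ei = 0, ej = 0;
  double best = local ? 0.0 : NEG_INF;
  if (local) {
    for (int i = 1; i <= n; i++)
      for (int j = 1; j <= m; j++)
        if (H[at(i, j)] > best) { best = H[at(i, j)]; ei = i; ej = j; }
  } else {
    for (int j = 0; j <= m; j++)
      if (H[at(n, j)] > best) { best = H[at(n, j)]; ei = n; ej = j; }
    for (int i = 0; i < n; i++)
      if (H[at(i, m)] > best) { best = H[at(i, m)]; ei = i; ej = m; }
  }

  // traceback
  std::vector<OpRun> rev;
  int i = ei, j = ej;
  while (i > 0 && j > 0) {
    double h = H[at(i, j)];
    if (local && h == 0.0) break;
    double s = (query[i - 1] == ref[j - 1]) ? match : -mismatch;
    if (h == H[at(i - 1, j - 1)] + s) {
      push_op(rev, (query[i - 1] == ref[j - 1]) ? 'M' : 'X');
      i--; j--;
    } else if (h == E[at(i, j)]) {
      // deletion run: walk left while the run extends
      while (true) {
        push_op(rev, 'D');
        double e = E[at(i, j)];
        j--;
        if (j == 0) break;
        if (e == E[at(i, j)] - gap_extend) continue;   // run continues
        // run opened from H[i][j]
        break;
      }
    } else {
      // insertion run: walk up
      while (true) {
        push_op(rev, 'I');
        double f = F[at(i, j)];
        i--;
        if (i == 0) break;
        if (f == F[at(i, j)] - gap_extend) continue;
        break;
      }
    }
  }

  int qs = i, rs = j;  // 0-based alignment starts
  // ops were collected in reverse
  int k = (int) rev.size();
  CharacterVector op(k);
  IntegerVector len(k);
  for (int t = 0; t < k; t++) {
    op[t] = std::string(1, rev[k - 1 - t].op);
    len[t] = rev[k - 1 - t].len;
  }

  return List::create(
    _["score"] = best,
    _["op"] = op,
    _["len"] = len,
    _["query_start"] = qs,
    _["query_end"] = ei,
    _["ref_start"] = rs,
    _["ref_end"] = ej
  );
}
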