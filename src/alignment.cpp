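#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Protein sequence alignment by dynamic programming with affine gaps.
// Sequences arrive as 1-based integer indices into the substitution matrix.
// Gap cost convention: a gap of length L costs open + L * extend (the first
// gap position pays both the opening and one extension).

static const double NEG = -1e18;

// Smith-Waterman local alignment score (score only, linear memory).
// E = gap in query (consumes subject, row-local); F = gap in subject
// (consumes query, column-wise).
static double sw_score_one(const int* q, int m, const int* s, int n,
                           const IntegerMatrix& sub, double go, double ge) {
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0), Fcol(n + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    double Erow = NEG;
    for (int j = 1; j <= n; ++j) {
      Erow = std::max(Hcur[j - 1] - go - ge, Erow - ge);
      Fcol[j] = std::max(Hprev[j] - go - ge, Fcol[j] - ge);
      double h = Hprev[j - 1] + sub(q[i - 1] - 1, s[j - 1] - 1);
      if (Erow > h) h = Erow;
      if (Fcol[j] > h) h = Fcol[j];
      if (h < 0) h = 0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// [[Rcpp::export]]
double cpp_sw_score(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                    double gap_open, double gap_extend) {
  return sw_score_one(q.begin(), q.size(), s.begin(), s.size(), sub,
                      gap_open, gap_extend);
}

// Local-alignment scores of one query against a list of subjects.
// [[Rcpp::export]]
NumericVector cpp_sw_scores(IntegerVector q, List subjects, IntegerMatrix sub,
                            double gap_open, double gap_extend) {
  int ns = subjects.size();
  NumericVector out(ns);
  for (int k = 0; k < ns; ++k) {
    IntegerVector s = subjects[k];
    out[k] = sw_score_one(q.begin(), q.size(), s.begin(), s.size(), sub,
                          gap_open, gap_extend);
  }
  return out;
}

// Global-local (semi-global) alignment: the query is aligned end to end,
// the subject's ends are free. Full-matrix DP with affine gaps and a
// deterministic traceback (diagonal > up > left; gaps close as early as
// possible). Returns the score, the edit operations (0 = match/mismatch
// column, 1 = query residue vs gap, 2 = gap vs subject residue) and the
// 1-based subject span consumed by the alignment.
// [[Rcpp::export]]
List cpp_semiglobal(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                    double gap_open, double gap_extend) {
  int m = q.size(), n = s.size();
  const double go = gap_open, ge = gap_extend, eps = 1e-6;
  std::vector<double> H((m + 1) * (n + 1)), E((m + 1) * (n + 1)),
      F((m + 1) * (n + 1));
  #define IX(i, j) ((i) * (n + 1) + (j))
  for (int j = 0; j <= n; ++j) {
    H[IX(0, j)] = 0.0; E[IX(0, j)] = NEG; F[IX(0, j)] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    H[IX(i, 0)] = -(go + i * ge);
    F[IX(i, 0)] = -(go + i * ge);
    E[IX(i, 0)] = NEG;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[IX(i, j)] = std::max(H[IX(i, j - 1)] - go - ge,
                             E[IX(i, j - 1)] - ge);
      F[IX(i, j)] = std::max(H[IX(i - 1, j)] - go - ge,
                             F[IX(i - 1, j)] - ge);
      double h = H[IX(i - 1, j - 1)] + sub(q[i - 1] - 1, s[j - 1] - 1);
      if (F[IX(i, j)] > h) h = F[IX(i, j)];
      if (E[IX(i, j)] > h) h = E[IX(i, j)];
      H[IX(i, j)] = h;
    }
  }
  int jend = 0;
  double best = H[IX(m, 0)];
  for (int j = 1; j <= n; ++j)
    if (H[IX(m, j)] > best + 1e-9) { best = H[IX(m, j)]; jend = j; }

  std::vector<int> ops;
  int i = m, j = jend, state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
  while (i > 0) {
    if (state == 0) {
      double h = H[IX(i, j)];
      if (j > 0 &&
          std::fabs(h - (H[IX(i - 1, j - 1)] +
                         sub(q[i - 1] - 1, s[j - 1] - 1))) < eps) {
        ops.push_back(0); --i; --j;
      } else if (std::fabs(h - F[IX(i, j)]) < eps) {
        state = 1;
      } else if (j > 0 && std::fabs(h - E[IX(i, j)]) < eps) {
        state = 2;
      } else {
        stop("semiglobal traceback failure");
      }
    } else if (state == 1) {
      double f = F[IX(i, j)];
      ops.push_back(1);
      if (std::fabs(f - (H[IX(i - 1, j)] - go - ge)) < eps) state = 0;
      --i;
    } else {
      double e = E[IX(i, j)];
      ops.push_back(2);
      if (std::fabs(e - (H[IX(i, j - 1)] - go - ge)) < eps) state = 0;
      --j;
    }
  }
  #undef IX
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["subject_start"] = j + 1,
                      _["subject_end"] = jend);
}
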