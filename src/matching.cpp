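#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fragment-mass matching and the one-unknown-shift proteoform search.
// All masses are neutral monoisotopic Da; tolerances are relative (ppm of
// the theoretical mass being matched).

static inline double tolw(double m, double tol_ppm) {
  return tol_ppm * 1e-6 * std::fabs(m);
}

// Greedy left-to-right one-to-one pairing: iterate theoretical masses in
// ascending order; each consumes the smallest unconsumed observed mass
// within tolerance. For sorted lists with interval compatibility this
// greedy attains the maximum one-to-one matching.
// [[Rcpp::export]]
int cpp_greedy_match(NumericVector theo, NumericVector obs, double tol_ppm) {
  int j = 0, n = obs.size(), count = 0;
  for (int i = 0; i < theo.size(); ++i) {
    double t = theo[i];
    if (t <= 0) continue;
    double w = tolw(t, tol_ppm);
    while (j < n && obs[j] < t - w) ++j;
    if (j < n && obs[j] <= t + w) { ++count; ++j; }
  }
  return count;
}

struct Item { double mass; int site; bool shifted; bool nterm; };

// Exact best-split scoring for one unknown shift. theoN[u-1] is the
// N-terminal ladder mass at cleavage site u (ascending); theoC[u-1] the
// C-terminal ladder mass at site u (descending in u). For split site s the
// shift is assumed to lie at residue s+1 or later: N-terminal sites > s and
// C-terminal sites <= s carry +delta. Score per split is the greedy
// one-to-one match count over the combined ladder. Returns the best score
// (smallest split wins ties) and the localization interval [first,last]:
// first = 1 + rightmost matched site bounding the shift from the left
// (unshifted N or shifted C evidence), last = leftmost matched site bounding
// it from the right (shifted N or unshifted C), defaulting to the segment
// termini when evidence is absent.
static void one_shift_core(const std::vector<double>& theoN,
                           const std::vector<double>& theoC,
                           int seg_len, const double* obs, int nobs,
                           double delta, double tol_ppm,
                           int& out_score, int& out_first, int& out_last) {
  int best_score = -1, best_r = 0, best_t = seg_len;
  std::vector<Item> items;
  items.reserve(theoN.size() + theoC.size());
  for (int s = 0; s <= seg_len - 1; ++s) {
    items.clear();
    for (int u = 1; u <= (int)theoN.size(); ++u) {
      bool sh = u > s;
      double m = theoN[u - 1] + (sh ? delta : 0.0);
      if (m > 0) items.push_back(Item{m, u, sh, true});
    }
    for (int u = 1; u <= (int)theoC.size(); ++u) {
      bool sh = u <= s;
      double m = theoC[u - 1] + (sh ? delta : 0.0);
      if (m > 0) items.push_back(Item{m, u, sh, false});
    }
    std::sort(items.begin(), items.end(),
              [](const Item& a, const Item& b) { return a.mass < b.mass; });
    int j = 0, score = 0, rmax = 0, tmin = seg_len + 1;
    for (size_t k = 0; k < items.size(); ++k) {
      const Item& it = items[k];
      double w = tolw(it.mass, tol_ppm);
      while (j < nobs && obs[j] < it.mass - w) ++j;
      if (j < nobs && obs[j] <= it.mass + w) {
        ++score; ++j;
        bool lower = (it.nterm && !it.shifted) || (!it.nterm && it.shifted);
        if (lower) { if (it.site > rmax) rmax = it.site; }
        else       { if (it.site < tmin) tmin = it.site; }
      }
    }
    if (score > best_score) {
      best_score = score;
      best_r = rmax;
      best_t = (tmin <= seg_len ? tmin : seg_len);
    }
  }
  out_score = best_score;
  out_first = best_r + 1;
  out_last = best_t;
}

// [[Rcpp::export]]
List cpp_one_shift(NumericVector theoN, NumericVector theoC, int seg_len,
                   NumericVector obs, double delta, double tol_ppm) {
  std::vector<double> tn(theoN.begin(), theoN.end());
  std::vector<double> tc(theoC.begin(), theoC.end());
  int score, first, last;
  one_shift_core(tn, tc, seg_len, obs.begin(), obs.size(), delta, tol_ppm,
                 score, first, last);
  return List::create(_["score"] = score, _["first"] = first,
                      _["last"] = last);
}

// flag pass: does any observed mass lie within tolerance of m?
// (non-consuming; ptr advances monotonically over ascending m)
static inline bool flag_hit(double m, const double* obs, int nobs, int& ptr,
                            double tol_ppm) {
  if (m <= 0) return false;
  double w = tolw(m, tol_ppm);
  while (ptr < nobs && obs[ptr] < m - w) ++ptr;
  return (ptr < nobs && obs[ptr] <= m + w);
}

// Best proteoform-spectrum match over every terminally truncated segment of
// every database protein whose unmodified mass lies within
// [precursor - max_delta, precursor + max_delta]. prefixes[p] is the
// cumulative residue-mass vector of protein p (length L+1, leading 0).
// Proteins must be supplied in ascending id order; ties on (score, |delta|)
// keep the earliest candidate, giving the deterministic tie-break
// higher score > smaller |delta| > smallest (protein, start, end).
// Candidates within the precursor tolerance of a zero shift are scored as
// unmodified matches (no shift interval); all others by the exact one-shift
// split search, pre-screened with a cheap upper bound (per-site match flags
// without one-to-one consumption, maximized over splits).
// [[Rcpp::export]]
List cpp_search_db(List prefixes, NumericVector obs, double precursor,
                   double tol_ppm, double max_delta, int min_len,
                   double water, bool use_n, bool use_c) {
  int np = prefixes.size();
  int nobs = obs.size();
  const double* ob = obs.begin();
  double prec_w = tolw(precursor, tol_ppm);

  int b_prot = -1, b_start = 0, b_end = 0, b_first = 0, b_last = 0,
      b_score = -1;
  double b_absd = R_PosInf, b_delta = 0;
  bool b_zero = false;

  std::vector<double> theoN, theoC, comb;
  std::vector<char> fUN, fSN, fUC, fSC;

  if (min_len < 2) min_len = 2;

  for (int p = 0; p < np; ++p) {
    NumericVector P = prefixes[p];
    int L = P.size() - 1;
    for (int i = 1; i + min_len - 1 <= L; ++i) {
      double base = P[i - 1];
      double lo = precursor - max_delta - water + base;
      double hi = precursor + max_delta - water + base;
      int jmin = i + min_len - 1;
      int j1 = (int)(std::lower_bound(P.begin() + jmin, P.begin() + L + 1, lo)
                     - P.begin());
      for (int j = j1; j <= L; ++j) {
        if (P[j] > hi) break;
        int seg_len = j - i + 1;
        int nsites = seg_len - 1;
        double M = P[j] - base + water;
        double delta = precursor - M;
        double absd = std::fabs(delta);

        theoN.resize(nsites); theoC.resize(nsites);
        for (int u = 1; u <= nsites; ++u) {
          theoN[u - 1] = P[i + u - 1] - base;
          theoC[u - 1] = M - theoN[u - 1];
        }

        int score, first = 0, last = 0;
        bool zero = (absd <= prec_w);
        if (zero) {
          // unmodified candidate: single greedy pass on the merged ladder
          comb.clear();
          if (use_n) comb.insert(comb.end(), theoN.begin(), theoN.end());
          if (use_c) comb.insert(comb.end(), theoC.rbegin(), theoC.rend());
          std::sort(comb.begin(), comb.end());
          int jj = 0; score = 0;
          for (size_t k = 0; k < comb.size(); ++k) {
            double w = tolw(comb[k], tol_ppm);
            while (jj < nobs && ob[jj] < comb[k] - w) ++jj;
            if (jj < nobs && ob[jj] <= comb[k] + w) { ++score; ++jj; }
          }
        } else {
          // upper bound: per-site flags (no consumption), best split by
          // prefix sums
          fUN.assign(nsites + 1, 0); fSN.assign(nsites + 1, 0);
          fUC.assign(nsites + 1, 0); fSC.assign(nsites + 1, 0);
          int p1 = 0, p2 = 0, p3 = 0, p4 = 0;
          if (use_n) {
            for (int u = 1; u <= nsites; ++u)
              fUN[u] = flag_hit(theoN[u - 1], ob, nobs, p1, tol_ppm);
            for (int u = 1; u <= nsites; ++u)
              fSN[u] = flag_hit(theoN[u - 1] + delta, ob, nobs, p2, tol_ppm);
          }
          if (use_c) {
            for (int u = nsites; u >= 1; --u)
              fUC[u] = flag_hit(theoC[u - 1], ob, nobs, p3, tol_ppm);
            for (int u = nsites; u >= 1; --u)
              fSC[u] = flag_hit(theoC[u - 1] + delta, ob, nobs, p4, tol_ppm);
          }
          // A[s] = matched unshifted N sites <= s, etc.
          int sumSN = 0, sumUC = 0;
          for (int u = 1; u <= nsites; ++u) { sumSN += fSN[u]; sumUC += fUC[u]; }
          int A = 0, Cc = 0, B = sumSN, D = sumUC, ub = -1;
          for (int s = 0; s <= seg_len - 1; ++s) {
            if (s >= 1 && s <= nsites) {
              A += fUN[s]; Cc += fSC[s];
              B -= fSN[s]; D -= fUC[s];
            }
            int v = A + B + Cc + D;
            if (v > ub) ub = v;
          }
          if (ub < b_score || (ub == b_score && absd >= b_absd)) continue;
          std::vector<double> tn = use_n ? theoN : std::vector<double>();
          std::vector<double> tc = use_c ? theoC : std::vector<double>();
          one_shift_core(tn, tc, seg_len, ob, nobs, delta, tol_ppm,
                         score, first, last);
        }

        bool better = (score > b_score) ||
                      (score == b_score && absd < b_absd);
        if (better) {
          b_prot = p; b_start = i; b_end = j; b_score = score;
          b_delta = delta; b_absd = absd; b_zero = zero;
          b_first = zero ? 0 : first; b_last = zero ? 0 : last;
        }
      }
    }
  }
  return List::create(_["iprot"] = b_prot + 1, _["start"] = b_start,
                      _["end"] = b_end, _["score"] = b_score,
                      _["delta"] = b_delta, _["zero"] = b_zero,
                      _["first"] = b_first, _["last"] = b_last);
}
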