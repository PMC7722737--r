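#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs and separately
// priced end gaps. Traceback tie-break: diagonal, then gap-in-b (consume a),
// then gap-in-a. Matches are counted along the tie-broken optimal path.
//
// H(i,j) = best score aligning a[1..i] with b[1..j], leading end gaps priced
// at `end_gap` per column in the initial row/column; trailing end gaps are
// priced when choosing the final cell on the last row/column.

struct NWOut {
  double score;
  int matches;
  int columns;       // aligned length incl. end gaps
  std::string a_aln;
  std::string b_aln;
};

static NWOut nw_full(const std::string& a, const std::string& b,
                     double match, double mismatch, double gap,
                     double end_gap, bool traceback) {
  const int n = a.size(), m = b.size();
  std::vector<double> H((n + 1) * (m + 1));
  std::vector<int> M((n + 1) * (m + 1));
  std::vector<signed char> P((n + 1) * (m + 1)); // 0 origin, 1 diag, 2 up, 3 left
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  for (int i = 0; i <= n; ++i) { H[at(i, 0)] = end_gap * i; M[at(i, 0)] = 0; P[at(i, 0)] = i ? 2 : 0; }
  for (int j = 1; j <= m; ++j) { H[at(0, j)] = end_gap * j; M[at(0, j)] = 0; P[at(0, j)] = 3; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      const double d = H[at(i - 1, j - 1)] + (eq ? match : mismatch);
      const double u = H[at(i - 1, j)] + gap;
      const double l = H[at(i, j - 1)] + gap;
      if (d >= u && d >= l) {
        H[at(i, j)] = d; P[at(i, j)] = 1; M[at(i, j)] = M[at(i - 1, j - 1)] + (eq ? 1 : 0);
      } else if (u >= l) {
        H[at(i, j)] = u; P[at(i, j)] = 2; M[at(i, j)] = M[at(i - 1, j)];
      } else {
        H[at(i, j)] = l; P[at(i, j)] = 3; M[at(i, j)] = M[at(i, j - 1)];
      }
    }
  }

  // Final cell: anywhere on the last row/column, remaining columns are
  // trailing end gaps at end_gap each. Ties: higher match count, then the
  // cell closest to (n, m).
  int bi = n, bj = m;
  double best = H[at(n, m)];
  int bestM = M[at(n, m)];
  for (int i = 0; i < n; ++i) {
    double s = H[at(i, m)] + end_gap * (n - i);
    if (s > best || (s == best && M[at(i, m)] > bestM)) { best = s; bestM = M[at(i, m)]; bi = i; bj = m; }
  }
  for (int j = 0; j < m; ++j) {
    double s = H[at(n, j)] + end_gap * (m - j);
    if (s > best || (s == best && M[at(n, j)] > bestM)) { best = s; bestM = M[at(n, j)]; bi = n; bj = j; }
  }

  NWOut out;
  out.score = best;
  out.matches = bestM;
  out.columns = 0;
  if (traceback) {
    std::string ra, rb;
    // trailing end gaps
    for (int i = n; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
    for (int j = m; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
    int i = bi, j = bj;
    while (i > 0 || j > 0) {
      signed char p = P[at(i, j)];
      if (p == 1) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; }
      else if (p == 2) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
      else { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    out.a_aln = ra;
    out.b_aln = rb;
    out.columns = (int) ra.size();
  }
  return out;
}

// Rolling two-row score+match DP, no traceback: used for the all-pairs
// drivers where only (score, matches) are needed. Only valid for
// end_gap == 0 fast path? No: handles general end_gap too.
static void nw_score_only(const std::string& a, const std::string& b,
                          double match, double mismatch, double gap,
                          double end_gap, double& score, int& matches) {
  const int n = a.size(), m = b.size();
  std::vector<double> h0(m + 1), h1(m + 1);
  std::vector<int> m0(m + 1), m1(m + 1);
  for (int j = 0; j <= m; ++j) { h0[j] = end_gap * j; m0[j] = 0; }
  double best = h0[m] + end_gap * n; // end at (0, m)
  int bestM = 0;
  // also track last row at the end
  for (int i = 1; i <= n; ++i) {
    h1[0] = end_gap * i; m1[0] = 0;
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      const double d = h0[j - 1] + (eq ? match : mismatch);
      const double u = h0[j] + gap;
      const double l = h1[j - 1] + gap;
      if (d >= u && d >= l) { h1[j] = d; m1[j] = m0[j - 1] + (eq ? 1 : 0); }
      else if (u >= l) { h1[j] = u; m1[j] = m0[j]; }
      else { h1[j] = l; m1[j] = m1[j - 1]; }
    }
    double s = h1[m] + end_gap * (n - i);
    if (s > best || (s == best && m1[m] > bestM)) { best = s; bestM = m1[m]; }
    std::swap(h0, h1); std::swap(m0, m1);
  }
  // last row (h0 after final swap)
  for (int j = 0; j <= m; ++j) {
    double s = h0[j] + end_gap * (m - j);
    if (s > best || (s == best && m0[j] > bestM)) { best = s; bestM = m0[j]; }
  }
  score = best;
  matches = bestM;
}

// [[Rcpp::export]]
List nw_pair_cpp(std::string a, std::string b, double match, double mismatch,
                 double gap, double end_gap) {
  NWOut o = nw_full(a, b, match, mismatch, gap, end_gap, true);
  return List::create(_["score"] = o.score, _["matches"] = o.matches,
                      _["columns"] = o.columns,
                      _["a_aln"] = o.a_aln, _["b_aln"] = o.b_aln);
}

// [[Rcpp::export]]
List nw_all_pairs_cpp(CharacterVector seqs, double match, double mismatch,
                      double gap, double end_gap) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix score(n, n);
  IntegerMatrix matches(n, n);
  for (int i = 0; i < n; ++i) {
    score(i, i) = s[i].size() * match;
    matches(i, i) = s[i].size();
    for (int j = i + 1; j < n; ++j) {
      double sc; int mt;
      nw_score_only(s[i], s[j], match, mismatch, gap, end_gap, sc, mt);
      score(i, j) = score(j, i) = sc;
      matches(i, j) = matches(j, i) = mt;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["matches"] = matches);
}

// [[Rcpp::export]]
List nw_cross_cpp(CharacterVector qry, CharacterVector ref, double match,
                  double mismatch, double gap, double end_gap) {
  const int n = qry.size(), m = ref.size();
  std::vector<std::string> q(n), r(m);
  for (int i = 0; i < n; ++i) q[i] = as<std::string>(qry[i]);
  for (int j = 0; j < m; ++j) r[j] = as<std::string>(ref[j]);
  NumericMatrix score(n, m);
  IntegerMatrix matches(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double sc; int mt;
      nw_score_only(q[i], r[j], match, mismatch, gap, end_gap, sc, mt);
      score(i, j) = sc;
      matches(i, j) = mt;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["matches"] = matches);
}
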