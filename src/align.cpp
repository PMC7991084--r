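#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state DP.
// Gap of length L costs open + (L-1) * extend (penalties passed as positive
// integers).  Traceback tie-break: diagonal over up (gap in seq2) over left
// (gap in seq1), fixed so identity counts are deterministic.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct AlnStats {
  double score;
  int n_columns;
  int n_identity;
};

// Reusable DP workspace so batch calls avoid per-pair heap allocation.
struct NWWork {
  std::vector<double> M, X, Y;
  std::vector<int> r1, r2;
  int cols;
  double& m(int i, int j) { return M[i * cols + j]; }
  double& x(int i, int j) { return X[i * cols + j]; }
  double& y(int i, int j) { return Y[i * cols + j]; }
  void resize(int n, int mm) {
    cols = mm + 1;
    size_t need = (size_t)(n + 1) * cols;
    if (M.size() < need) { M.resize(need); X.resize(need); Y.resize(need); }
  }
};

static AlnStats nw_align_int(const int* s1, int n, const int* s2, int m,
                             const int* sub, int open, int extend,
                             NWWork& w, bool keep_alignment) {
  w.resize(n, m);
  w.m(0, 0) = 0.0; w.x(0, 0) = NEG_INF; w.y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; i++) {
    w.m(i, 0) = NEG_INF; w.y(i, 0) = NEG_INF;
    w.x(i, 0) = -(double)(open + (i - 1) * extend);
  }
  for (int j = 1; j <= m; j++) {
    w.m(0, j) = NEG_INF; w.x(0, j) = NEG_INF;
    w.y(0, j) = -(double)(open + (j - 1) * extend);
  }
  for (int i = 1; i <= n; i++) {
    const int a = s1[i - 1] * 20;
    for (int j = 1; j <= m; j++) {
      double s = (double)sub[a + s2[j - 1]];
      double best = std::max(w.m(i - 1, j - 1),
                             std::max(w.x(i - 1, j - 1), w.y(i - 1, j - 1)));
      w.m(i, j) = best + s;
      w.x(i, j) = std::max(std::max(w.m(i - 1, j), w.y(i - 1, j)) - open,
                           w.x(i - 1, j) - extend);
      w.y(i, j) = std::max(std::max(w.m(i, j - 1), w.x(i, j - 1)) - open,
                           w.y(i, j - 1) - extend);
    }
  }
  AlnStats res;
  res.score = std::max(w.m(n, m), std::max(w.x(n, m), w.y(n, m)));

  // traceback; state: 0 = M, 1 = X, 2 = Y; prefer lower state on ties
  int i = n, j = m, state;
  if (w.m(n, m) >= w.x(n, m) && w.m(n, m) >= w.y(n, m)) state = 0;
  else if (w.x(n, m) >= w.y(n, m)) state = 1;
  else state = 2;
  int ncols = 0, nid = 0;
  w.r1.clear(); w.r2.clear();
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      if (s1[i - 1] == s2[j - 1]) nid++;
      if (keep_alignment) { w.r1.push_back(s1[i - 1]); w.r2.push_back(s2[j - 1]); }
      double prev = w.m(i, j) - (double)sub[s1[i - 1] * 20 + s2[j - 1]];
      i--; j--;
      if (std::abs(w.m(i, j) - prev) < eps) state = 0;
      else if (std::abs(w.x(i, j) - prev) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (keep_alignment) { w.r1.push_back(s1[i - 1]); w.r2.push_back(-1); }
      double cur = w.x(i, j);
      i--;
      if (std::abs(w.m(i, j) - open - cur) < eps) state = 0;
      else if (std::abs(w.y(i, j) - open - cur) < eps) state = 2;
      else state = 1;
    } else {
      if (keep_alignment) { w.r1.push_back(-1); w.r2.push_back(s2[j - 1]); }
      double cur = w.y(i, j);
      j--;
      if (std::abs(w.m(i, j) - open - cur) < eps) state = 0;
      else if (std::abs(w.x(i, j) - open - cur) < eps) state = 1;
      else state = 2;
    }
    ncols++;
  }
  res.n_columns = ncols;
  res.n_identity = nid;
  return res;
}

// [[Rcpp::export]]
List cpp_nw_align(IntegerVector s1, IntegerVector s2, IntegerMatrix sub,
                  int open, int extend) {
  NWWork w;
  AlnStats r = nw_align_int(&s1[0], s1.size(), &s2[0], s2.size(),
                            &sub[0], open, extend, w, true);
  std::reverse(w.r1.begin(), w.r1.end());
  std::reverse(w.r2.begin(), w.r2.end());
  return List::create(_["score"] = r.score,
                      _["n_columns"] = r.n_columns,
                      _["n_identity"] = r.n_identity,
                      _["a1"] = IntegerVector(w.r1.begin(), w.r1.end()),
                      _["a2"] = IntegerVector(w.r2.begin(), w.r2.end()));
}

// Batch NW over all pairs; returns score, column-count and identity-count
// matrices (same traceback tie-break as the scalar path).  symmetric = true
// computes the upper triangle only and mirrors it.
// [[Rcpp::export]]
List cpp_nw_stats_matrix(List seqs1, List seqs2, IntegerMatrix sub,
                         int open, int extend, bool symmetric) {
  const int n1 = seqs1.size(), n2 = seqs2.size();
  std::vector<std::vector<int>> a(n1), b(n2);
  for (int i = 0; i < n1; i++)
    a[i] = as<std::vector<int>>(seqs1[i]);
  for (int j = 0; j < n2; j++)
    b[j] = as<std::vector<int>>(seqs2[j]);
  NumericMatrix score(n1, n2);
  IntegerMatrix ncol_(n1, n2), nid(n1, n2);
  NWWork w;
  for (int i = 0; i < n1; i++) {
    for (int j = symmetric ? i : 0; j < n2; j++) {
      AlnStats r = nw_align_int(a[i].data(), a[i].size(), b[j].data(),
                                b[j].size(), &sub[0], open, extend, w, false);
      score(i, j) = r.score; ncol_(i, j) = r.n_columns; nid(i, j) = r.n_identity;
      if (symmetric && j != i) {
        score(j, i) = r.score; ncol_(j, i) = r.n_columns; nid(j, i) = r.n_identity;
      }
    }
  }
  return List::create(_["score"] = score, _["n_columns"] = ncol_,
                      _["n_identity"] = nid);
}

// CDR3-only TCRdist: minimum over global alignments of the summed per-column
// cost, where an aligned pair (a, b) costs 0 if a == b and otherwise
// max(0, min(cap, cap - blosum62(a, b))), and each gapped column costs
// gap_penalty.  Linear (per-column) gap cost, plain DP.
static double tcrdist_int(const int* s1, int n, const int* s2, int m,
                          const double* cost, int gap,
                          std::vector<double>& prev, std::vector<double>& cur) {
  if ((int)prev.size() < m + 1) { prev.resize(m + 1); cur.resize(m + 1); }
  for (int j = 0; j <= m; j++) prev[j] = (double)j * gap;
  for (int i = 1; i <= n; i++) {
    cur[0] = (double)i * gap;
    const int a = s1[i - 1] * 20;
    for (int j = 1; j <= m; j++) {
      double c = cost[a + s2[j - 1]];
      double v = prev[j - 1] + c;
      double u = prev[j] + gap;
      if (u < v) v = u;
      u = cur[j - 1] + gap;
      if (u < v) v = u;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static std::vector<double> tcrdist_costs(const IntegerMatrix& sub, int cap) {
  std::vector<double> cost(400);
  for (int a = 0; a < 20; a++)
    for (int b = 0; b < 20; b++) {
      double c = (a == b) ? 0.0
        : std::min((double)cap, (double)cap - (double)sub(a, b));
      cost[a * 20 + b] = c < 0.0 ? 0.0 : c;
    }
  return cost;
}

// [[Rcpp::export]]
double cpp_tcrdist(IntegerVector s1, IntegerVector s2, IntegerMatrix sub,
                   int cap, int gap) {
  std::vector<double> prev, cur;
  std::vector<double> cost = tcrdist_costs(sub, cap);
  return tcrdist_int(&s1[0], s1.size(), &s2[0], s2.size(), cost.data(), gap,
                     prev, cur);
}

// [[Rcpp::export]]
NumericMatrix cpp_tcrdist_matrix(List seqs1, List seqs2, IntegerMatrix sub,
                                 int cap, int gap, bool symmetric) {
  const int n1 = seqs1.size(), n2 = seqs2.size();
  std::vector<std::vector<int>> a(n1), b(n2);
  for (int i = 0; i < n1; i++) a[i] = as<std::vector<int>>(seqs1[i]);
  for (int j = 0; j < n2; j++) b[j] = as<std::vector<int>>(seqs2[j]);
  std::vector<double> cost = tcrdist_costs(sub, cap);
  NumericMatrix out(n1, n2);
  std::vector<double> prev, cur;
  for (int i = 0; i < n1; i++) {
    for (int j = symmetric ? i : 0; j < n2; j++) {
      double d = tcrdist_int(a[i].data(), a[i].size(), b[j].data(),
                             b[j].size(), cost.data(), gap, prev, cur);
      out(i, j) = d;
      if (symmetric && j != i) out(j, i) = d;
    }
  }
  return out;
}
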