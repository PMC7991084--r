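#include <Rcpp.h>
using namespace Rcpp;

// k-mer kernel over two integer-encoded sequences (codes 0..19).
//
// K(s, t) = sum over k = 1..min(|s|,|t|), over all contiguous k-mers x of s
// and y of t, of prod_i m(x_i, y_i).  Every k-mer pair lies on one alignment
// offset ("diagonal"); on a diagonal with consecutive matched-position values
// m_1..m_L, the recurrence S_j = m_j * (1 + S_{j-1}) accumulates the products
// of all contiguous runs ending at j, so sum_j S_j counts every (start, k)
// exactly once.  Total cost O(|s| * |t|).
static double kernel_raw_int(const int* s1, int n, const int* s2, int n2,
                             const double* m) {
  double total = 0.0;
  for (int d = -(n - 1); d < n2; d++) {
    int i = d < 0 ? -d : 0;      // start index in s1
    int j = d < 0 ? 0 : d;       // start index in s2
    double S = 0.0;
    for (; i < n && j < n2; i++, j++) {
      S = m[s1[i] * 20 + s2[j]] * (1.0 + S);
      total += S;
    }
  }
  return total;
}

// [[Rcpp::export]]
double cpp_kernel_raw(IntegerVector s1, IntegerVector s2, NumericMatrix m) {
  // NumericMatrix is column-major; the kernel matrix is symmetric, so the
  // row-major indexing inside kernel_raw_int is equivalent.
  return kernel_raw_int(&s1[0], s1.size(), &s2[0], s2.size(), &m[0]);
}

// [[Rcpp::export]]
NumericMatrix cpp_kernel_score_matrix(List seqs1, List seqs2, NumericMatrix m,
                                      bool geometric, bool symmetric) {
  const int n1 = seqs1.size(), n2 = seqs2.size();
  std::vector<std::vector<int>> a(n1), b(n2);
  for (int i = 0; i < n1; i++) a[i] = as<std::vector<int>>(seqs1[i]);
  for (int j = 0; j < n2; j++) b[j] = as<std::vector<int>>(seqs2[j]);
  const double* mp = &m[0];
  std::vector<double> self1(n1), self2(n2);
  for (int i = 0; i < n1; i++)
    self1[i] = kernel_raw_int(a[i].data(), a[i].size(), a[i].data(),
                              a[i].size(), mp);
  for (int j = 0; j < n2; j++)
    self2[j] = kernel_raw_int(b[j].data(), b[j].size(), b[j].data(),
                              b[j].size(), mp);
  NumericMatrix out(n1, n2);
  for (int i = 0; i < n1; i++) {
    for (int j = symmetric ? i : 0; j < n2; j++) {
      double raw = kernel_raw_int(a[i].data(), a[i].size(), b[j].data(),
                                  b[j].size(), mp);
      double denom = geometric ? std::sqrt(self1[i] * self2[j])
                               : self1[i] * self2[j];
      out(i, j) = raw / denom;
      if (symmetric && j != i) out(j, i) = out(i, j);
    }
  }
  return out;
}
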