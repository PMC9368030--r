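#include <Rcpp.h>
using namespace Rcpp;

// Pairwise p-distances over an integer-coded alignment (0 = gap, >0 =
// residue code). d(i,j) = mismatches / compared sites over columns where
// neither row is gapped. A pair with zero comparable sites is marked -1 so
// the R wrapper can name it in its error message.
// [[Rcpp::export]]
NumericMatrix cpp_pdistance(IntegerMatrix codes) {
  const int n = codes.nrow(), L = codes.ncol();
  NumericMatrix d(n, n);
  // column-major access: copy rows into contiguous buffers
  std::vector<std::vector<int>> rows(n, std::vector<int>(L));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j) rows[i][j] = codes(i, j);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int *a = rows[i].data(), *b = rows[j].data();
      int comp = 0, mis = 0;
      for (int k = 0; k < L; ++k) {
        if (a[k] > 0 && b[k] > 0) {
          ++comp;
          if (a[k] != b[k]) ++mis;
        }
      }
      double v = comp == 0 ? -1.0 : (double)mis / comp;
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
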