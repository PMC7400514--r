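// Hot paths of the top-k aggregation: per-gene selection of the k largest
// tile scores (stable ties by tile index) and column-wise descending sort.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_topk")]]
List cpp_topk(NumericMatrix sc, int k) {
  const int n = sc.nrow(), G = sc.ncol();
  if (k > n) k = n;
  NumericVector means(G);
  IntegerMatrix idx(k, G);
  std::vector<int> ord(n);
  for (int g = 0; g < G; ++g) {
    const double *col = &sc(0, g);
    std::iota(ord.begin(), ord.end(), 0);
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [col](int a, int b) {
                        if (col[a] != col[b]) return col[a] > col[b];
                        return a < b;  // stable tie-break by tile index
                      });
    double s = 0.0;
    for (int i = 0; i < k; ++i) {
      idx(i, g) = ord[i] + 1;  // 1-based for R
      s += col[ord[i]];
    }
    means[g] = s / k;
  }
  return List::create(_["means"] = means, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_sort_desc_cols")]]
NumericMatrix cpp_sort_desc_cols(NumericMatrix sc) {
  const int n = sc.nrow(), G = sc.ncol();
  NumericMatrix out(n, G);
  std::vector<double> buf(n);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < n; ++i) buf[i] = sc(i, g);
    std::sort(buf.begin(), buf.end(), std::greater<double>());
    for (int i = 0; i < n; ++i) out(i, g) = buf[i];
  }
  return out;
}
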