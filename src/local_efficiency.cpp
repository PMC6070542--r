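#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted local efficiency (Onnela-style geometric means) of a symmetric
// non-negative weight matrix. For each node i with degree k >= 2, the
// shortest paths within the subgraph induced by i's neighbors are computed
// by Floyd-Warshall on edge lengths 1/w; the nodal efficiency is
//   1/(k(k-1)) * sum_{a != b} (w_ia * w_ib / d_ab)^(1/3),
// and the network value is the mean over all nodes.
// [[Rcpp::export(name = ".eloc_cpp")]]
double eloc_cpp(NumericMatrix W) {
  const int n = W.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  double total = 0.0;
  std::vector<int> nb;
  std::vector<double> D;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (W(i, j) > 0.0) nb.push_back(j);
    const int k = (int) nb.size();
    if (k < 2) continue;
    D.assign((size_t) k * k, inf);
    for (int a = 0; a < k; ++a) {
      D[a * k + a] = 0.0;
      for (int b = a + 1; b < k; ++b) {
        double w = W(nb[a], nb[b]);
        if (w > 0.0) {
          double len = 1.0 / w;
          D[a * k + b] = len;
          D[b * k + a] = len;
        }
      }
    }
    for (int m = 0; m < k; ++m)
      for (int a = 0; a < k; ++a) {
        double dam = D[a * k + m];
        if (!std::isfinite(dam)) continue;
        for (int b = 0; b < k; ++b) {
          double via = dam + D[m * k + b];
          if (via < D[a * k + b]) D[a * k + b] = via;
        }
      }
    double acc = 0.0;
    for (int a = 0; a < k; ++a) {
      double wa = W(i, nb[a]);
      for (int b = 0; b < k; ++b) {
        if (a == b) continue;
        double d = D[a * k + b];
        if (!std::isfinite(d) || d <= 0.0) continue;
        acc += std::cbrt(wa * W(i, nb[b]) / d);
      }
    }
    total += acc / ((double) k * (k - 1));
  }
  return total / n;
}
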