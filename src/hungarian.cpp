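// Dense minimum-cost assignment (Hungarian algorithm, Jonker-Volgenant
// shortest-augmenting-path formulation, O(n^3)).  Used for optimal
// one-to-one matching of detections to ground-truth centroids; forbidden
// pairs are encoded by the caller as a large finite cost.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Returns, for each row (1-based), the assigned column, on a square cost
// matrix.  Deterministic: scans columns in increasing index so cost ties
// resolve to the lowest column index reachable first.
// [[Rcpp::export(name = ".hungarian_cpp")]]
IntegerVector hungarian_cpp(const NumericMatrix& cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  // potentials and matching over 1..n with 0 as virtual index
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      const int i0 = p[j0];
      double delta = INF;
      int j1 = -1;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) {
    if (p[j] > 0) ans[p[j] - 1] = j;
  }
  return ans;
}
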