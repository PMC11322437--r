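// Connected-component labeling for binary masks (4- or 8-connectivity),
// iterative flood fill.  Labels are assigned in column-major scan order.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask,
                                   int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8) {
    stop("connectivity must be 4 or 8");
  }
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int rr = idx % nr, cc = idx / nr;
        for (int t = 0; t < nnb; ++t) {
          const int r2 = rr + dr8[t], c2 = cc + dc8[t];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + nr * c2);
          }
        }
      }
    }
  }
  return lab;
}
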