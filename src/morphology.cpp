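#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected component labelling of a binary mask (flood fill).
// Returns an integer matrix: 0 for background, 1..n for components.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        const int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          const int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
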