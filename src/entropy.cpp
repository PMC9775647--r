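#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window local Shannon entropy of an 8-bit channel raster.
//
// For every pixel (i, j) the (2k+1) x (2k+1) window centred there is
// intersected with the raster; the 256-bin gray-value histogram of the
// clipped window gives empirical probabilities p(v) = count(v) / n_window
// and H = -sum_v p(v) log p(v).  A row-wise incremental histogram makes the
// scan O(H * W * (2k+1) + H * W * 256) instead of O(H * W * (2k+1)^2).
//
// multiplicity = true evaluates the double sum over window *coordinates*
// instead (each value counted once per occurrence):
//   H_lit = -sum_v count(v) * p(v) * log p(v).
// values must lie in [0, 255]; log_base > 1.
// [[Rcpp::export]]
NumericMatrix local_entropy_sliding(IntegerMatrix img, int k,
                                    bool multiplicity, double log_base) {
  const int H = img.nrow(), W = img.ncol();
  if (k < 1) stop("window radius k must be >= 1");
  if (log_base <= 1.0) stop("log_base must be > 1");
  const double lb = std::log(log_base);
  NumericMatrix out(H, W);
  std::vector<int> hist(256);

  for (int i = 0; i < H; ++i) {
    const int r0 = std::max(0, i - k), r1 = std::min(H - 1, i + k);
    std::fill(hist.begin(), hist.end(), 0);
    int total = 0;
    // seed histogram with the window of column 0
    for (int c = 0; c <= std::min(W - 1, k); ++c)
      for (int r = r0; r <= r1; ++r) { ++hist[img(r, c)]; ++total; }
    for (int j = 0; j < W; ++j) {
      if (j > 0) {
        const int add = j + k, rem = j - k - 1;
        if (add < W)  for (int r = r0; r <= r1; ++r) { ++hist[img(r, add)]; ++total; }
        if (rem >= 0) for (int r = r0; r <= r1; ++r) { --hist[img(r, rem)]; --total; }
      }
      double h = 0.0;
      const double n = static_cast<double>(total);
      for (int v = 0; v < 256; ++v) {
        const int c = hist[v];
        if (c > 0) {
          const double p = c / n;
          h -= (multiplicity ? c * p : p) * std::log(p);
        }
      }
      out(i, j) = h / lb;
    }
  }
  return out;
}
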