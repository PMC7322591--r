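#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Symmetric, edge-inclusive reflection (… b a | a b c … | c b …),
// matching the padding used by the R-side Gaussian blur.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Per-pixel Shannon entropy (bits) of the intensity histogram in a centred
// n x n window. `binned` holds bin indices in [0, bins). Entropy is computed
// as log2(m) - sum(c * log2 c) / m over bin counts c, m = n^2, which avoids
// the 0 * log2(0) case entirely.
// [[Rcpp::export]]
NumericMatrix local_entropy_cpp(const IntegerMatrix& binned, int n, int bins) {
  const int H = binned.nrow(), W = binned.ncol(), r = n / 2, m = n * n;
  NumericMatrix out(H, W);

  std::vector<double> clog(m + 1, 0.0);
  for (int c = 2; c <= m; ++c) clog[c] = c * std::log2((double)c);
  const double log2m = std::log2((double)m);

  std::vector<int> hist(bins, 0);
  std::vector<int> touched;
  touched.reserve(m);

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      touched.clear();
      for (int dj = -r; dj <= r; ++dj) {
        const int cj = reflect_idx(j + dj, W);
        for (int di = -r; di <= r; ++di) {
          const int ci = reflect_idx(i + di, H);
          const int b = binned(ci, cj);
          if (hist[b]++ == 0) touched.push_back(b);
        }
      }
      double s = 0.0;
      for (size_t t = 0; t < touched.size(); ++t) {
        s += clog[hist[touched[t]]];
        hist[touched[t]] = 0;
      }
      double e = log2m - s / m;
      out(i, j) = e > 0.0 ? e : 0.0;
    }
  }
  return out;
}
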