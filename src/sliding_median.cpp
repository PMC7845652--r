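#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of a small window given as a scratch buffer (modified in place).
// Even-length windows use the mean of the two middle order statistics.
static double window_median(std::vector<double>& buf) {
  const size_t n = buf.size();
  const size_t mid = n / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
  double hi = buf[mid];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + mid);
  return 0.5 * (lo + hi);
}

// Sliding median with step one sample. The window is centred on the output
// sample; for even window lengths the centre is taken as floor(w/2), i.e.
// the window covers [i - w/2, i + w/2 - 1]. edge = 0 shrinks the window at
// the signal ends, edge = 1 reflects the signal about its end points.
// [[Rcpp::export(name = ".sliding_median_cpp")]]
NumericVector sliding_median_cpp(NumericVector x, int w, int edge) {
  const int n = x.size();
  if (w < 1) stop("window must be at least 1 sample");
  if (w > n) stop("window longer than signal");
  NumericVector out(n);
  const int left = w / 2;          // samples before centre
  const int right = w - left - 1;  // samples after centre
  std::vector<double> buf;
  buf.reserve(w);
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int j = i - left; j <= i + right; ++j) {
      int k = j;
      if (edge == 0) {
        if (k < 0 || k >= n) continue;
      } else {
        // reflect about the end points (no repeat of the edge sample)
        while (k < 0 || k >= n) {
          if (k < 0) k = -k;
          if (k >= n) k = 2 * (n - 1) - k;
        }
      }
      buf.push_back(x[k]);
    }
    out[i] = window_median(buf);
  }
  return out;
}
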