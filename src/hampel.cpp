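#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double window_median(std::vector<double> &buf) {
  size_t n = buf.size();
  size_t mid = n / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
  double m = buf[mid];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + mid);
    m = 0.5 * (m + lo);
  }
  return m;
}

// Sliding-window Hampel despiking. For each sample i the window is
// x[max(0,i-k) .. min(n-1,i+k)] (truncated at the edges); the sample is
// replaced by the window median when it deviates from it by more than
// n_sigmas * 1.4826 * MAD, where MAD is the median absolute deviation of the
// window about its own median.
// [[Rcpp::export(name = ".hampel_cpp")]]
NumericVector hampel_cpp(NumericVector x, int k, double n_sigmas) {
  int n = x.size();
  NumericVector out = clone(x);
  std::vector<double> buf, dev;
  buf.reserve(2 * k + 1);
  dev.reserve(2 * k + 1);
  const double kappa = 1.4826;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - k);
    int hi = std::min(n - 1, i + k);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    double med = window_median(buf);
    dev.resize(buf.size());
    for (size_t j = 0; j < buf.size(); ++j) dev[j] = std::fabs(buf[j] - med);
    double mad = window_median(dev);
    double thr = n_sigmas * kappa * mad;
    if (std::fabs(x[i] - med) > thr) out[i] = med;
  }
  return out;
}
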