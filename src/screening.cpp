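// Resampled range-capture rate: fraction of size-n resamples whose
// interpolated percentile interval reaches both endpoints of the global
// interval. Driven by R's RNG so results follow set.seed() on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// interpolated type-7 quantile pair (plo < phi) of the first n elements
// of buf, which are sorted in place as needed
static inline void q_pair(std::vector<double>& buf, int n, double plo,
                          double phi, double& qlo, double& qhi) {
  const double hlo = (n - 1) * plo, hhi = (n - 1) * phi;
  const int jlo = (int)std::floor(hlo), jhi = (int)std::floor(hhi);
  std::sort(buf.begin(), buf.begin() + n);
  const int jlo1 = std::min(n - 1, jlo + 1), jhi1 = std::min(n - 1, jhi + 1);
  qlo = buf[jlo] + (hlo - jlo) * (buf[jlo1] - buf[jlo]);
  qhi = buf[jhi] + (hhi - jhi) * (buf[jhi1] - buf[jhi]);
}

// [[Rcpp::export(name = ".capture_rate_cpp")]]
double capture_rate_cpp(const NumericVector& values, int n, int reps,
                        double lo_lim, double hi_lim, double plo,
                        double phi, bool replace) {
  RNGScope scope;
  const int N = values.size();
  std::vector<double> pool(values.begin(), values.end());
  std::vector<double> buf(n);
  int ok = 0;
  for (int r = 0; r < reps; ++r) {
    if (replace) {
      for (int i = 0; i < n; ++i) {
        int j = (int)std::floor(unif_rand() * N);
        if (j >= N) j = N - 1;
        buf[i] = pool[j];
      }
    } else {
      // partial Fisher-Yates: first n elements become the sample
      for (int i = 0; i < n; ++i) {
        int j = i + (int)std::floor(unif_rand() * (N - i));
        if (j >= N) j = N - 1;
        std::swap(pool[i], pool[j]);
        buf[i] = pool[i];
      }
    }
    double qlo, qhi;
    q_pair(buf, n, plo, phi, qlo, qhi);
    if (qlo <= lo_lim && qhi >= hi_lim) ++ok;
  }
  return (double)ok / reps;
}
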