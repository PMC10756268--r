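#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// xorshift64* PRNG: fast, seedable, identical across platforms, so training
// is bit-reproducible from the seed alone (single-worker contract)
static inline uint64_t rng_next(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double rng_u01(uint64_t &s) {
  return (rng_next(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 50.0) return 1.0;
  if (x < -50.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// One SGNS training epoch over a token stream.
//
// vin / vout are d x n matrices (one column per token), modified in place.
// flat: 0-based token indices, concatenated sentences; lens: sentence
// lengths.  noise_cdf: cumulative noise distribution for negative draws.
// processed_start / total_pairs drive the global linear learning-rate decay
// from alpha0 down to alpha0 * 1e-4.  Returns the updated processed count.
// [[Rcpp::export]]
double sgns_epoch_cpp(IntegerVector flat, IntegerVector lens,
                      NumericMatrix vin, NumericMatrix vout,
                      NumericVector noise_cdf,
                      int window, int negatives, double alpha0,
                      double processed_start, double total_pairs,
                      double seed) {
  const int d = vin.nrow();
  const int nvocab = vin.ncol();
  double *in = REAL(vin);
  double *out = REAL(vout);
  const double *cdf = REAL(noise_cdf);
  const int *tok = INTEGER(flat);
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;
  std::vector<double> grad(d);
  double processed = processed_start;
  int offset = 0;
  for (int s = 0; s < lens.size(); ++s) {
    const int len = lens[s];
    for (int t = 0; t < len; ++t) {
      const int center = tok[offset + t];
      const int lo = t - window < 0 ? 0 : t - window;
      const int hi = t + window >= len ? len - 1 : t + window;
      for (int c = lo; c <= hi; ++c) {
        if (c == t) continue;
        const int context = tok[offset + c];
        double frac = processed / total_pairs;
        if (frac > 1.0) frac = 1.0;
        const double lr = alpha0 * ((1.0 - frac) + frac * 1e-4);
        processed += 1.0;
        double *v = in + (size_t)center * d;
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int m = 0; m <= negatives; ++m) {
          int target;
          double label;
          if (m == 0) {
            target = context;
            label = 1.0;
          } else {
            const double u = rng_u01(rng);
            // binary search in the noise CDF
            int a = 0, b = nvocab - 1;
            while (a < b) {
              const int mid = (a + b) / 2;
              if (cdf[mid] < u) a = mid + 1; else b = mid;
            }
            target = a;
            label = 0.0;
          }
          double *uvec = out + (size_t)target * d;
          double f = 0.0;
          for (int q = 0; q < d; ++q) f += uvec[q] * v[q];
          const double g = (label - sigmoid(f)) * lr;
          for (int q = 0; q < d; ++q) {
            grad[q] += g * uvec[q];
            uvec[q] += g * v[q];
          }
        }
        for (int q = 0; q < d; ++q) v[q] += grad[q];
      }
    }
    offset += len;
  }
  return processed;
}
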