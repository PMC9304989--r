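// Core photon-count simulation and correlation kernels.
//
// The speckle field at each SPAD pixel is modelled as a stationary circular
// complex Gaussian process. For an exponential field autocorrelation
// g1(tau) = exp(-tau/tau_c) the discrete-time process is an exact complex
// AR(1): E_t = rho E_{t-1} + sqrt(1-rho^2) xi_t with rho = exp(-dt/tau_c),
// which gives |g1(k dt)| = rho^k without any spectral truncation error.
// Detected counts are conditionally Poisson given the instantaneous
// intensity (shot-noise model for single-photon detection).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: a small, fast, reproducible
// generator that keeps the simulator independent of R's global RNG state.
struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Marsaglia polar method; caches the second variate of each pair.
struct NormalGen {
  Xoshiro256 &rng;
  bool has;
  double cached;
  explicit NormalGen(Xoshiro256 &r) : rng(r), has(false), cached(0.0) {}
  inline double operator()() {
    if (has) { has = false; return cached; }
    double v1, v2, rsq;
    do {
      v1 = 2.0 * rng.unif() - 1.0;
      v2 = 2.0 * rng.unif() - 1.0;
      rsq = v1 * v1 + v2 * v2;
    } while (rsq >= 1.0 || rsq == 0.0);
    double fac = std::sqrt(-2.0 * std::log(rsq) / rsq);
    cached = v2 * fac;
    has = true;
    return v1 * fac;
  }
};

// Poisson by CDF inversion; one uniform per draw. lam stays small here
// (photons per microsecond-scale bin), so the walk terminates quickly.
inline int rpois_inv(Xoshiro256 &rng, double lam) {
  if (lam <= 0.0) return 0;
  double u = rng.unif();
  // exp(-lam) >= 1 - lam, so u <= 1 - lam already decides k = 0 without
  // evaluating the exponential; at these photon rates that is almost every
  // bin. Identical draws: the same single uniform is consumed either way.
  if (u <= 1.0 - lam) return 0;
  double p = std::exp(-lam), F = p;
  int k = 0;
  while (u > F && k < 10000) { ++k; p *= lam / k; F += p; }
  return k;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_speckle_counts")]]
IntegerMatrix cpp_speckle_counts(int n_bins, NumericVector rho,
                                 NumericVector mean_rate, double beta,
                                 double dark_rate, double seed) {
  int n_pix = rho.size();
  if (mean_rate.size() != n_pix)
    stop("rho and mean_rate must have one entry per pixel");
  if (beta < 0.0 || beta > 1.0) stop("beta must lie in [0, 1]");
  Xoshiro256 rng((uint64_t) seed);
  NormalGen gauss(rng);
  IntegerMatrix out(n_bins, n_pix);
  const double s = std::sqrt(beta);
  const double half = std::sqrt(0.5);
  for (int p = 0; p < n_pix; ++p) {
    double rp = rho[p], rate = mean_rate[p];
    if (rp < 0.0 || rp >= 1.0) stop("per-pixel AR coefficient must be in [0, 1)");
    int *col = &out(0, p);
    if (rate <= 0.0) {
      // unmapped pixel: dark counts only
      for (int t = 0; t < n_bins; ++t) col[t] = rpois_inv(rng, dark_rate);
      continue;
    }
    const double innov = std::sqrt((1.0 - rp * rp) / 2.0);
    // stationary start: E ~ CN(0, 1)
    double er = gauss() * half, ei = gauss() * half;
    for (int t = 0; t < n_bins; ++t) {
      er = rp * er + innov * gauss();
      ei = rp * ei + innov * gauss();
      // normalized intensity with mean 1: X = |E|^2 / <|E|^2>, <|E|^2> = 1
      double X = er * er + ei * ei;
      // partial-coherence mixing so that g2 = 1 + beta |g1|^2
      double lam = rate * ((1.0 - s) + s * X) + dark_rate;
      col[t] = rpois_inv(rng, lam);
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_g2_counts")]]
NumericMatrix cpp_g2_counts(IntegerMatrix counts, IntegerVector lags,
                            bool symmetric) {
  int n = counts.nrow(), P = counts.ncol(), L = lags.size();
  for (int k = 0; k < L; ++k)
    if (lags[k] <= 0 || lags[k] >= n) stop("lags must lie strictly inside the window");
  NumericMatrix g2(L, P);
  // Photon-starved streams are mostly zeros, so the lagged cross products
  // only need the nonzero bins; segment sums come from one prefix pass.
  // All sums are exact integer arithmetic, independent of summation order.
  std::vector<long long> prefix(n + 1);
  std::vector<int> nz;
  nz.reserve(1024);
  for (int p = 0; p < P; ++p) {
    const int *col = &counts(0, p);
    prefix[0] = 0;
    nz.clear();
    for (int t = 0; t < n; ++t) {
      prefix[t + 1] = prefix[t] + col[t];
      if (col[t] != 0) nz.push_back(t);
    }
    long long tot = prefix[n];
    double mw = (double) tot / n; // whole-window mean
    for (int k = 0; k < L; ++k) {
      int lag = lags[k];
      int m = n - lag;
      long long sab = 0;
      for (size_t j = 0; j < nz.size(); ++j) {
        int t = nz[j];
        if (t >= m) break;
        sab += (long long) col[t] * col[t + lag];
      }
      long long sa = prefix[m];
      long long sb = tot - prefix[lag];
      double num = (double) sab / m;
      if (symmetric) {
        double ma = (double) sa / m, mb = (double) sb / m;
        g2(k, p) = (ma > 0.0 && mb > 0.0) ? num / (ma * mb) : NA_REAL;
      } else {
        g2(k, p) = (mw > 0.0) ? num / (mw * mw) : NA_REAL;
      }
    }
  }
  return g2;
}
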