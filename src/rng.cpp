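#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Seeded Gaussian deviates for large synthetic noise fields, independent of
// R's global RNG stream so that per-subject child seeds can be fanned out
// from one master seed without disturbing user code that uses set.seed().
//
// Generator: xoshiro256++ (Blackman & Vigna), seeded through splitmix64.
// Normals: Box-Muller on the raw 64-bit stream.

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
};

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    SplitMix64 sm(seed);
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1): top 53 bits, offset to exclude 0
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

}  // namespace

// [[Rcpp::export(name = ".rng_normal")]]
Rcpp::NumericVector rng_normal(double n, double seed) {
  R_xlen_t len = static_cast<R_xlen_t>(n);
  Rcpp::NumericVector out(len);
  Xoshiro256pp g(static_cast<uint64_t>(seed));
  const double twopi = 6.283185307179586476925286766559;
  R_xlen_t i = 0;
  while (i < len) {
    double u1 = g.unif();
    double u2 = g.unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    out[i++] = r * std::cos(twopi * u2);
    if (i < len) out[i++] = r * std::sin(twopi * u2);
  }
  return out;
}

// [[Rcpp::export(name = ".rng_unif")]]
Rcpp::NumericVector rng_unif(double n, double seed) {
  R_xlen_t len = static_cast<R_xlen_t>(n);
  Rcpp::NumericVector out(len);
  Xoshiro256pp g(static_cast<uint64_t>(seed));
  for (R_xlen_t i = 0; i < len; ++i) out[i] = g.unif();
  return out;
}

// Deterministic 64-bit hash of (master seed, stream path) -> child seed,
// returned as a double exactly representable below 2^53.
// [[Rcpp::export(name = ".rng_child_seed")]]
double rng_child_seed(double master, Rcpp::NumericVector path) {
  SplitMix64 sm(static_cast<uint64_t>(master) ^ 0x51f15eedULL);
  uint64_t h = sm.next();
  for (R_xlen_t i = 0; i < path.size(); ++i) {
    h ^= static_cast<uint64_t>(path[i]) + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    SplitMix64 mix(h);
    h = mix.next();
  }
  return static_cast<double>(h >> 11);  // < 2^53
}
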