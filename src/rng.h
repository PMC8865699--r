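#ifndef ENGRAMNET_RNG_H
#define ENGRAMNET_RNG_H

#include <cstdint>
#include <cmath>
#include <vector>

// Self-contained xoshiro256++ generator so that the construction, external
// drive and rewiring streams can be seeded independently and reproduce
// bit-identically across platforms and R sessions.
struct XoshiroRNG {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit XoshiroRNG(uint64_t seed = 1) { reseed(seed); }

  void reseed(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
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

  // uniform double in [0, 1)
  double runif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in [0, n), Lemire's multiply-shift with rejection
  uint32_t bounded(uint32_t n) {
    uint64_t m = (uint64_t)(uint32_t)next() * (uint64_t)n;
    uint32_t l = (uint32_t)m;
    if (l < n) {
      uint32_t t = (0u - n) % n;
      while (l < t) {
        m = (uint64_t)(uint32_t)next() * (uint64_t)n;
        l = (uint32_t)m;
      }
    }
    return (uint32_t)(m >> 32);
  }

  // Poisson count by Knuth's product-of-uniforms; all rates used per step
  // are small (<= ~12 events), where this is both exact and fast.
  int rpois(double exp_neg_lambda) {
    int k = 0;
    double p = 1.0;
    do {
      ++k;
      p *= runif();
    } while (p > exp_neg_lambda);
    return k - 1;
  }

  template <typename T>
  void shuffle(std::vector<T> &v) {
    for (size_t i = v.size(); i > 1; --i) {
      size_t j = bounded((uint32_t)i);
      std::swap(v[i - 1], v[j]);
    }
  }
};

#endif
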