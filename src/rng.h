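#ifndef KMERBETA_RNG_H
#define KMERBETA_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained deterministic RNG (splitmix64-seeded xoshiro256++) so that
// read simulation is bit-reproducible across platforms and compilers.
// Standard-library distributions are implementation-defined and are avoided.

namespace kmerbeta {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

class Xoshiro256pp {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
public:
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer on [0, n); multiplicative (Lemire) mapping, bias < n/2^64
  uint64_t unif_int(uint64_t n) {
    return (uint64_t)(((__uint128_t)next() * (__uint128_t)n) >> 64);
  }
  // standard normal via Box-Muller (no cached spare: deterministic call order)
  double normal() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

// seeded 64-bit mixing hash used for bottom-s sketching
inline uint64_t hash_kmer(uint64_t key, uint64_t seed) {
  uint64_t x = key + (seed + 1) * 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

} // namespace kmerbeta

#endif
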