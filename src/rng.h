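#ifndef EICORR_RNG_H
#define EICORR_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded RNG so that simulations are reproducible
// from a single integer seed, independent of R's RNG state.
// xoshiro256++ (public-domain algorithm) seeded via splitmix64.
struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64 step
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1)
  inline double u01() {
    return (next() >> 11) * 0x1.0p-53 + 0x1.0p-54;
  }

  // standard normal via Marsaglia polar method, with caching
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * u01() - 1.0;
      v = 2.0 * u01() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

#endif
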