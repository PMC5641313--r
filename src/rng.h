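#ifndef SBSFOLD_RNG_H
#define SBSFOLD_RNG_H

#include <cstdint>
#include <cmath>

// Small self-contained counter-seeded generator (splitmix64 -> xoshiro256**)
// so that trajectories are reproducible from an integer seed independently of
// R's global RNG state.
struct SbsRng {
  uint64_t s[4];
  bool have_gauss;
  double gauss_cache;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit SbsRng(uint64_t seed) : have_gauss(false), gauss_cache(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  int unif_int(int n) {  // uniform on {0, ..., n-1}
    return (int)(unif() * n) % n;
  }

  // standard normal, Box-Muller (portable across platforms)
  double gauss() {
    if (have_gauss) {
      have_gauss = false;
      return gauss_cache;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    gauss_cache = r * std::sin(a);
    have_gauss = true;
    return r * std::cos(a);
  }
};

#endif
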