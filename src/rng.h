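#ifndef IPDPOP_RNG_H
#define IPDPOP_RNG_H

// xoshiro256** with splitmix64 seeding. A self-contained counter-seeded
// stream keeps batches of simulations reproducible and cheap; each
// replicate gets its own stream derived from (base seed, replicate index).

#include <cstdint>

namespace ipdpop_rng {

inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // returns 0 (=C) with probability p_coop, else 1 (=D)
  int move_bern(double p_coop) { return unif() < p_coop ? 0 : 1; }
  int ri(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// stream seed for replicate k of a batch
inline uint64_t stream_seed(double base, int k) {
  uint64_t x = static_cast<uint64_t>(base) ^ (0xD1B54A32D192ED03ULL * (static_cast<uint64_t>(k) + 1));
  return splitmix64(x);
}

}  // namespace ipdpop_rng

#endif
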