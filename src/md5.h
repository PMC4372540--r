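#ifndef IPDPOP_MD5_H
#define IPDPOP_MD5_H

// Compact MD5 (RFC 1321). Used only for the information player's
// deterministic tie-break; assumes a little-endian host.

#include <cstdint>
#include <cstring>
#include <cmath>
#include <string>
#include <vector>

namespace ipdpop_md5 {

inline uint32_t rotl32(uint32_t x, int c) { return (x << c) | (x >> (32 - c)); }

inline const uint32_t* sine_table() {
  static uint32_t K[64];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 64; ++i)
      K[i] = static_cast<uint32_t>(std::floor(std::fabs(std::sin(i + 1.0)) * 4294967296.0));
    init = true;
  }
  return K;
}

inline void md5(const unsigned char* data, size_t len, unsigned char out[16]) {
  static const int S[64] = {
    7, 12, 17, 22, 7, 12, 17, 22, 7, 12, 17, 22, 7, 12, 17, 22,
    5, 9, 14, 20, 5, 9, 14, 20, 5, 9, 14, 20, 5, 9, 14, 20,
    4, 11, 16, 23, 4, 11, 16, 23, 4, 11, 16, 23, 4, 11, 16, 23,
    6, 10, 15, 21, 6, 10, 15, 21, 6, 10, 15, 21, 6, 10, 15, 21};
  const uint32_t* K = sine_table();
  uint32_t a0 = 0x67452301u, b0 = 0xefcdab89u, c0 = 0x98badcfeu, d0 = 0x10325476u;

  size_t padded = ((len + 8) / 64 + 1) * 64;
  std::vector<unsigned char> msg(padded, 0);
  if (len) std::memcpy(msg.data(), data, len);
  msg[len] = 0x80;
  uint64_t bitlen = static_cast<uint64_t>(len) * 8;
  std::memcpy(msg.data() + padded - 8, &bitlen, 8);

  for (size_t off = 0; off < padded; off += 64) {
    uint32_t M[16];
    for (int i = 0; i < 16; ++i) std::memcpy(&M[i], msg.data() + off + 4 * i, 4);
    uint32_t A = a0, B = b0, C = c0, D = d0;
    for (int i = 0; i < 64; ++i) {
      uint32_t F;
      int g;
      if (i < 16)      { F = (B & C) | (~B & D); g = i; }
      else if (i < 32) { F = (D & B) | (~D & C); g = (5 * i + 1) % 16; }
      else if (i < 48) { F = B ^ C ^ D;          g = (3 * i + 5) % 16; }
      else             { F = C ^ (B | ~D);       g = (7 * i) % 16; }
      F = F + A + K[i] + M[g];
      A = D; D = C; C = B;
      B = B + rotl32(F, S[i]);
    }
    a0 += A; b0 += B; c0 += C; d0 += D;
  }
  std::memcpy(out, &a0, 4);
  std::memcpy(out + 4, &b0, 4);
  std::memcpy(out + 8, &c0, 4);
  std::memcpy(out + 12, &d0, 4);
}

// least-significant bit of the final digest byte
inline int md5_lsb(const std::string& s) {
  unsigned char d[16];
  md5(reinterpret_cast<const unsigned char*>(s.data()), s.size(), d);
  return d[15] & 1;
}

inline std::string md5_hex(const std::string& s) {
  unsigned char d[16];
  md5(reinterpret_cast<const unsigned char*>(s.data()), s.size(), d);
  static const char* hx = "0123456789abcdef";
  std::string out(32, '0');
  for (int i = 0; i < 16; ++i) {
    out[2 * i] = hx[d[i] >> 4];
    out[2 * i + 1] = hx[d[i] & 0xf];
  }
  return out;
}

}  // namespace ipdpop_md5

#endif
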