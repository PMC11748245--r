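// AES-256 block cipher with CBC chaining.
//
// The S-box, its inverse and the round constants are derived at load time
// from GF(2^8) arithmetic (multiplicative inverse + affine map) instead of
// being transcribed, so a single typo cannot silently corrupt the cipher;
// correctness is pinned against FIPS-197-style known-answer vectors in the
// test suite.

#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

namespace {

typedef unsigned char u8;
typedef unsigned int u32;

static u8 SBOX[256];
static u8 INV_SBOX[256];
static u8 MUL9[256], MUL11[256], MUL13[256], MUL14[256];
// standard 32-bit round tables (encryption Te, decryption Td)
static u32 TE0[256], TE1[256], TE2[256], TE3[256];
static u32 TD0[256], TD1[256], TD2[256], TD3[256];
static bool tables_ready = false;

inline u8 xtime(u8 x) { return (u8)((x << 1) ^ ((x & 0x80) ? 0x1b : 0x00)); }

inline u8 gmul(u8 a, u8 b) {
  u8 p = 0;
  while (b) {
    if (b & 1) p ^= a;
    a = xtime(a);
    b >>= 1;
  }
  return p;
}

void build_tables() {
  if (tables_ready) return;
  // multiplicative inverses in GF(2^8) via brute force (256*256 once)
  u8 inv[256];
  inv[0] = 0;
  for (int a = 1; a < 256; ++a)
    for (int b = 1; b < 256; ++b)
      if (gmul((u8)a, (u8)b) == 1) { inv[a] = (u8)b; break; }
  for (int x = 0; x < 256; ++x) {
    u8 c = inv[x], s = 0;
    for (int i = 0; i < 8; ++i) {
      u8 bit = (u8)(((c >> i) & 1) ^ ((c >> ((i + 4) % 8)) & 1) ^
                    ((c >> ((i + 5) % 8)) & 1) ^ ((c >> ((i + 6) % 8)) & 1) ^
                    ((c >> ((i + 7) % 8)) & 1) ^ ((0x63 >> i) & 1));
      s |= (u8)(bit << i);
    }
    SBOX[x] = s;
  }
  for (int x = 0; x < 256; ++x) INV_SBOX[SBOX[x]] = (u8)x;
  for (int x = 0; x < 256; ++x) {
    MUL9[x] = gmul((u8)x, 9);
    MUL11[x] = gmul((u8)x, 11);
    MUL13[x] = gmul((u8)x, 13);
    MUL14[x] = gmul((u8)x, 14);
  }
  for (int x = 0; x < 256; ++x) {
    u8 s = SBOX[x];
    u32 te = ((u32)gmul(s, 2)) | ((u32)s << 8) | ((u32)s << 16) |
             ((u32)gmul(s, 3) << 24);
    TE0[x] = te;
    TE1[x] = (te << 8) | (te >> 24);
    TE2[x] = (te << 16) | (te >> 16);
    TE3[x] = (te << 24) | (te >> 8);
    u8 si = INV_SBOX[x];
    u32 td = ((u32)MUL14[si]) | ((u32)MUL9[si] << 8) | ((u32)MUL13[si] << 16) |
             ((u32)MUL11[si] << 24);
    TD0[x] = td;
    TD1[x] = (td << 8) | (td >> 24);
    TD2[x] = (td << 16) | (td >> 16);
    TD3[x] = (td << 24) | (td >> 8);
  }
  tables_ready = true;
}

// AES-256: Nk = 8, Nr = 14, expanded key = 60 words
void key_expansion(const u8 *key, u8 *rk) {
  const int Nk = 8, Nr = 14;
  std::memcpy(rk, key, 4 * Nk);
  u8 rcon = 1;
  for (int i = Nk; i < 4 * (Nr + 1); ++i) {
    u8 t[4];
    std::memcpy(t, rk + 4 * (i - 1), 4);
    if (i % Nk == 0) {
      u8 tmp = t[0];
      t[0] = (u8)(SBOX[t[1]] ^ rcon);
      t[1] = SBOX[t[2]];
      t[2] = SBOX[t[3]];
      t[3] = SBOX[tmp];
      rcon = xtime(rcon);
    } else if (i % Nk == 4) {
      for (int k = 0; k < 4; ++k) t[k] = SBOX[t[k]];
    }
    for (int k = 0; k < 4; ++k) rk[4 * i + k] = (u8)(rk[4 * (i - Nk) + k] ^ t[k]);
  }
}

inline u32 load32(const u8 *p) {
  return (u32)p[0] | ((u32)p[1] << 8) | ((u32)p[2] << 16) | ((u32)p[3] << 24);
}

inline void store32(u8 *p, u32 w) {
  p[0] = (u8)w;
  p[1] = (u8)(w >> 8);
  p[2] = (u8)(w >> 16);
  p[3] = (u8)(w >> 24);
}

// T-table round function; state words are the little-endian column words
void encrypt_block(const u8 *in, u8 *out, const u8 *rk) {
  const int Nr = 14;
  u32 s[4], t[4];
  for (int c = 0; c < 4; ++c) s[c] = load32(in + 4 * c) ^ load32(rk + 4 * c);
  for (int round = 1; round < Nr; ++round) {
    const u8 *k = rk + 16 * round;
    for (int c = 0; c < 4; ++c)
      t[c] = TE0[(u8)s[c]] ^ TE1[(u8)(s[(c + 1) & 3] >> 8)] ^
             TE2[(u8)(s[(c + 2) & 3] >> 16)] ^
             TE3[(u8)(s[(c + 3) & 3] >> 24)] ^ load32(k + 4 * c);
    std::memcpy(s, t, 16);
  }
  const u8 *k = rk + 16 * Nr;
  for (int c = 0; c < 4; ++c) {
    u32 w = (u32)SBOX[(u8)s[c]] | ((u32)SBOX[(u8)(s[(c + 1) & 3] >> 8)] << 8) |
            ((u32)SBOX[(u8)(s[(c + 2) & 3] >> 16)] << 16) |
            ((u32)SBOX[(u8)(s[(c + 3) & 3] >> 24)] << 24);
    store32(out + 4 * c, w ^ load32(k + 4 * c));
  }
}

// decryption round keys: InvMixColumns-transformed encryption schedule
void make_decrypt_keys(const u8 *rk, u32 *dk) {
  const int Nr = 14;
  for (int c = 0; c < 4; ++c) dk[c] = load32(rk + 16 * Nr + 4 * c);
  for (int round = 1; round < Nr; ++round) {
    const u8 *k = rk + 16 * (Nr - round);
    for (int c = 0; c < 4; ++c) {
      u32 w = load32(k + 4 * c);
      dk[4 * round + c] = TD0[SBOX[(u8)w]] ^ TD1[SBOX[(u8)(w >> 8)]] ^
                          TD2[SBOX[(u8)(w >> 16)]] ^ TD3[SBOX[(u8)(w >> 24)]];
    }
  }
  for (int c = 0; c < 4; ++c) dk[4 * Nr + c] = load32(rk + 4 * c);
}

void decrypt_block(const u8 *in, u8 *out, const u32 *dk) {
  const int Nr = 14;
  u32 s[4], t[4];
  for (int c = 0; c < 4; ++c) s[c] = load32(in + 4 * c) ^ dk[c];
  for (int round = 1; round < Nr; ++round) {
    const u32 *k = dk + 4 * round;
    for (int c = 0; c < 4; ++c)
      t[c] = TD0[(u8)s[c]] ^ TD1[(u8)(s[(c + 3) & 3] >> 8)] ^
             TD2[(u8)(s[(c + 2) & 3] >> 16)] ^
             TD3[(u8)(s[(c + 1) & 3] >> 24)] ^ k[c];
    std::memcpy(s, t, 16);
  }
  const u32 *k = dk + 4 * Nr;
  for (int c = 0; c < 4; ++c) {
    u32 w = (u32)INV_SBOX[(u8)s[c]] |
            ((u32)INV_SBOX[(u8)(s[(c + 3) & 3] >> 8)] << 8) |
            ((u32)INV_SBOX[(u8)(s[(c + 2) & 3] >> 16)] << 16) |
            ((u32)INV_SBOX[(u8)(s[(c + 1) & 3] >> 24)] << 24);
    store32(out + 4 * c, w ^ k[c]);
  }
}

}  // namespace

// [[Rcpp::export(name = ".aes256_cbc_encrypt")]]
RawVector aes256_cbc_encrypt(RawVector plaintext, RawVector key, RawVector iv) {
  build_tables();
  if (key.size() != 32) stop("AES-256 key must be exactly 32 bytes");
  if (iv.size() != 16) stop("IV must be exactly 16 bytes");
  if (plaintext.size() % 16 != 0)
    stop("plaintext must be padded to a multiple of 16 bytes");
  u8 rk[16 * 15];
  key_expansion(RAW(key), rk);
  R_xlen_t n = plaintext.size();
  RawVector out(n);
  u8 chain[16];
  std::memcpy(chain, RAW(iv), 16);
  const u8 *in = RAW(plaintext);
  u8 *dst = RAW(out);
  u8 blk[16];
  for (R_xlen_t off = 0; off < n; off += 16) {
    for (int i = 0; i < 16; ++i) blk[i] = (u8)(in[off + i] ^ chain[i]);
    encrypt_block(blk, dst + off, rk);
    std::memcpy(chain, dst + off, 16);
  }
  return out;
}

// [[Rcpp::export(name = ".aes256_cbc_decrypt")]]
RawVector aes256_cbc_decrypt(RawVector ciphertext, RawVector key, RawVector iv) {
  build_tables();
  if (key.size() != 32) stop("AES-256 key must be exactly 32 bytes");
  if (iv.size() != 16) stop("IV must be exactly 16 bytes");
  if (ciphertext.size() == 0 || ciphertext.size() % 16 != 0)
    stop("ciphertext length must be a positive multiple of 16 bytes");
  u8 rk[16 * 15];
  key_expansion(RAW(key), rk);
  u32 dk[4 * 15];
  make_decrypt_keys(rk, dk);
  R_xlen_t n = ciphertext.size();
  RawVector out(n);
  u8 chain[16];
  std::memcpy(chain, RAW(iv), 16);
  const u8 *in = RAW(ciphertext);
  u8 *dst = RAW(out);
  for (R_xlen_t off = 0; off < n; off += 16) {
    decrypt_block(in + off, dst + off, dk);
    for (int i = 0; i < 16; ++i) dst[off + i] ^= chain[i];
    std::memcpy(chain, in + off, 16);
  }
  return out;
}
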