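#ifndef KMERBIN_COMMON_H
#define KMERBIN_COMMON_H

#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <string>
#include <vector>

namespace kb {

// base codes: A=0, C=1, G=2, T=3 so that integer order equals
// lexicographic order with A<C<G<T; -1 marks a non-ACGT symbol
inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char code_base(int c) { return "ACGT"[c & 3]; }

inline std::vector<int8_t> to_codes(const std::string& s) {
  std::vector<int8_t> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = (int8_t) base_code(s[i]);
  return out;
}

inline std::string codes_to_string(const int8_t* c, int n) {
  std::string s(n, 'A');
  for (int i = 0; i < n; ++i) s[i] = code_base(c[i]);
  return s;
}

inline void revcomp_codes(const int8_t* in, int n, int8_t* out) {
  for (int i = 0; i < n; ++i) out[i] = (int8_t)(3 - in[n - 1 - i]);
}

// byte packing: base j sits in byte j/4, first base of each byte in the
// two most significant bits, so byte-wise comparison of equal-length
// packed sequences equals lexicographic comparison
inline std::vector<uint8_t> pack_bytes(const int8_t* c, int n) {
  std::vector<uint8_t> out((n + 3) / 4, 0);
  for (int j = 0; j < n; ++j)
    out[j >> 2] |= (uint8_t)(c[j] << (2 * (3 - (j & 3))));
  return out;
}

inline void unpack_bytes(const uint8_t* b, int n, int8_t* out) {
  for (int j = 0; j < n; ++j)
    out[j] = (int8_t)((b[j >> 2] >> (2 * (3 - (j & 3)))) & 3);
}

// word packing for hashing and hash-table keys: 32 bases per 64-bit word,
// first base in the most significant bit pair; trailing bits zero
inline int nwords_for(int k) { return (k + 31) / 32; }

inline void pack_words(const int8_t* c, int k, uint64_t* out) {
  int nw = nwords_for(k);
  for (int w = 0; w < nw; ++w) out[w] = 0;
  for (int j = 0; j < k; ++j)
    out[j >> 5] |= ((uint64_t)(c[j] & 3)) << (62 - 2 * (j & 31));
}

inline void unpack_words(const uint64_t* w, int k, int8_t* out) {
  for (int j = 0; j < k; ++j)
    out[j] = (int8_t)((w[j >> 5] >> (62 - 2 * (j & 31))) & 3);
}

// 64-bit avalanche mixer (multiply-xor-shift; splitmix64 finalizer)
inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// probing hash: consumes successive 64-bit blocks (32 bases each);
// running time linear in k
inline uint64_t probe_hash64(const uint64_t* words, int k) {
  int nw = nwords_for(k);
  uint64_t h = 0x8445d61a4e774912ULL ^ ((uint64_t)k * 0x9e3779b97f4a7c15ULL);
  for (int w = 0; w < nw; ++w) h = mix64(h ^ words[w]);
  return h;
}

// partition hash: consumes at most the first four 16-bit blocks
// (8 bases each); constant-time contract regardless of k
inline uint32_t part_hash16(const uint64_t* words, int k) {
  int nblocks = (k + 7) / 8;
  if (nblocks > 4) nblocks = 4;
  uint64_t h = 0x2545f4914f6cdd1dULL ^ (uint64_t)k;
  for (int b = 0; b < nblocks; ++b) {
    uint32_t blk = (uint32_t)((words[b >> 2] >> (48 - 16 * (b & 3))) & 0xffffULL);
    h = mix64(h ^ blk);
  }
  return (uint32_t)(h & 0xffffULL);
}

// quadratic (triangular) probe schedule; covers every slot when the
// capacity is a power of two
inline uint64_t probe_slot(uint64_t h0, uint64_t i, uint64_t capacity) {
  return (h0 + (i + i * i) / 2) % capacity;
}

inline uint64_t round_pow2(uint64_t x) {
  uint64_t c = 1;
  while (c < x) c <<= 1;
  return c;
}

// canonical form of a k-mer given as codes: writes min(x, revcomp(x))
// into out (out may alias neither input)
inline void canonical_codes(const int8_t* c, int k, int8_t* out) {
  // lexicographic compare of x vs rc(x) without materializing rc
  int cmp = 0;
  for (int i = 0; i < k; ++i) {
    int rc = 3 - c[k - 1 - i];
    if (c[i] != rc) { cmp = (c[i] < rc) ? -1 : 1; break; }
  }
  if (cmp <= 0) {
    for (int i = 0; i < k; ++i) out[i] = c[i];
  } else {
    revcomp_codes(c, k, out);
  }
}

// maximal ACGT runs of a coded sequence
struct Fragment { int start; int len; };

inline std::vector<Fragment> fragments_of(const std::vector<int8_t>& codes) {
  std::vector<Fragment> out;
  int n = (int)codes.size();
  int i = 0;
  while (i < n) {
    if (codes[i] < 0) { ++i; continue; }
    int j = i;
    while (j < n && codes[j] >= 0) ++j;
    out.push_back({i, j - i});
    i = j;
  }
  return out;
}

// super-mer decomposition of one ACGT fragment --------------------------

struct SuperMer {
  int start;      // base offset within fragment
  int len;        // length in bases (>= k)
  uint32_t rank;  // rank of the shared minimizer
};

// occurrence of the minimal m-mer: (rank, position, strand); strand 0 =
// forward, 1 = reverse complement; ties broken by leftmost position,
// forward preferred
struct MinOcc {
  uint32_t rank;
  int pos;
  int strand;
};

// decompose a fragment (codes, all >= 0) into super-mers under the given
// rank table (length 4^m, a bijection onto [0, 4^m))
inline void decompose(const int8_t* c, int L, int k, int m,
                      const int* ranks, bool canonical,
                      std::vector<SuperMer>& out) {
  if (L < k) return;
  int nmw = L - m + 1;  // m-mer windows
  std::vector<uint32_t> fwd((size_t)nmw), rev;
  uint64_t mask = ((uint64_t)1 << (2 * m)) - 1;
  uint64_t v = 0;
  for (int j = 0; j < m; ++j) v = (v << 2) | (uint64_t)c[j];
  fwd[0] = (uint32_t)ranks[v];
  uint64_t vv = v;
  for (int j = 1; j < nmw; ++j) {
    vv = ((vv << 2) | (uint64_t)c[j + m - 1]) & mask;
    fwd[j] = (uint32_t)ranks[vv];
  }
  if (canonical) {
    rev.resize((size_t)nmw);
    uint64_t r = 0;
    for (int j = 0; j < m; ++j)
      r |= ((uint64_t)(3 - c[j])) << (2 * j);
    rev[0] = (uint32_t)ranks[r];
    for (int j = 1; j < nmw; ++j) {
      r = (r >> 2) | (((uint64_t)(3 - c[j + m - 1])) << (2 * (m - 1)));
      rev[j] = (uint32_t)ranks[r];
    }
  }

  int span = k - m;  // candidate positions per k-window: s .. s+span
  MinOcc cur{0, -1, 0};
  int sm_start = 0;
  for (int s = 0; s + k <= L; ++s) {
    MinOcc best{fwd[s], s, 0};
    for (int j = s; j <= s + span; ++j) {
      if (fwd[j] < best.rank) best = {fwd[j], j, 0};
      if (canonical && rev[j] < best.rank) best = {rev[j], j, 1};
    }
    if (s == 0) {
      cur = best;
      sm_start = 0;
    } else if (best.pos != cur.pos || best.strand != cur.strand) {
      out.push_back({sm_start, (s - 1) + k - sm_start, cur.rank});
      cur = best;
      sm_start = s;
    }
  }
  out.push_back({sm_start, L - sm_start, cur.rank});
}

// temporary bin file record IO ------------------------------------------
// record: u16 LE base length, u32 LE minimizer rank, ceil(len/4) packed bytes

inline void write_record(FILE* f, const int8_t* c, int len, uint32_t rank) {
  uint8_t hdr[6];
  hdr[0] = (uint8_t)(len & 0xff);
  hdr[1] = (uint8_t)((len >> 8) & 0xff);
  hdr[2] = (uint8_t)(rank & 0xff);
  hdr[3] = (uint8_t)((rank >> 8) & 0xff);
  hdr[4] = (uint8_t)((rank >> 16) & 0xff);
  hdr[5] = (uint8_t)((rank >> 24) & 0xff);
  std::vector<uint8_t> packed = pack_bytes(c, len);
  if (std::fwrite(hdr, 1, 6, f) != 6 ||
      (packed.size() > 0 &&
       std::fwrite(packed.data(), 1, packed.size(), f) != packed.size()))
    Rcpp::stop("write error on temporary bin file");
}

// returns false on clean EOF; throws on a truncated record
inline bool read_record(FILE* f, std::vector<int8_t>& codes, uint32_t& rank) {
  uint8_t hdr[6];
  size_t got = std::fread(hdr, 1, 6, f);
  if (got == 0) return false;
  if (got != 6) Rcpp::stop("truncated record header in bin file");
  int len = (int)hdr[0] | ((int)hdr[1] << 8);
  rank = (uint32_t)hdr[2] | ((uint32_t)hdr[3] << 8) |
         ((uint32_t)hdr[4] << 16) | ((uint32_t)hdr[5] << 24);
  int nb = (len + 3) / 4;
  std::vector<uint8_t> buf((size_t)nb);
  if (nb > 0 && (int)std::fread(buf.data(), 1, (size_t)nb, f) != nb)
    Rcpp::stop("truncated record body in bin file");
  codes.resize((size_t)len);
  unpack_bytes(buf.data(), len, codes.data());
  return true;
}

// multiplicative (Knuth) hash of the rank, reduced mod F: scatters
// neighbouring ranks while keeping bin occupancy over a contiguous rank
// range exactly balanced whenever F is a power of two (the map is then a
// bijection mod F)
inline uint64_t assign_file64(uint32_t rank, uint64_t F) {
  return (((uint64_t)rank * 0x9e3779b1ULL) & 0xffffffffULL) % F;
}

}  // namespace kb

#endif
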