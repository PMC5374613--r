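#include "common.h"
using namespace Rcpp;

// binary count file: u64 LE record count, then per record ceil(k/4)
// packed k-mer bytes followed by a u32 LE count (saturating)

static void put_u64(FILE* f, uint64_t v) {
  uint8_t b[8];
  for (int i = 0; i < 8; ++i) b[i] = (uint8_t)((v >> (8 * i)) & 0xff);
  if (std::fwrite(b, 1, 8, f) != 8) stop("write error on count file");
}

static uint64_t get_u64(FILE* f) {
  uint8_t b[8];
  if (std::fread(b, 1, 8, f) != 8) stop("truncated count file header");
  uint64_t v = 0;
  for (int i = 0; i < 8; ++i) v |= ((uint64_t)b[i]) << (8 * i);
  return v;
}

// [[Rcpp::export]]
void cpp_write_counts_bin(std::string path, CharacterVector kmers,
                          NumericVector counts) {
  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  put_u64(f, (uint64_t)kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    std::vector<int8_t> codes = kb::to_codes(s);
    for (size_t j = 0; j < codes.size(); ++j)
      if (codes[j] < 0) { std::fclose(f); stop("non-ACGT base in k-mer"); }
    std::vector<uint8_t> packed = kb::pack_bytes(codes.data(), (int)codes.size());
    double cd = counts[i];
    uint32_t c = cd >= 4294967295.0 ? UINT32_MAX : (uint32_t)cd;
    uint8_t cb[4] = {(uint8_t)(c & 0xff), (uint8_t)((c >> 8) & 0xff),
                     (uint8_t)((c >> 16) & 0xff), (uint8_t)((c >> 24) & 0xff)};
    if ((packed.size() > 0 &&
         std::fwrite(packed.data(), 1, packed.size(), f) != packed.size()) ||
        std::fwrite(cb, 1, 4, f) != 4) {
      std::fclose(f);
      stop("write error on count file");
    }
  }
  std::fclose(f);
}

// [[Rcpp::export]]
List cpp_read_counts_bin(std::string path, int k) {
  if (k < 1) stop("k must be >= 1");
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s' for reading", path.c_str());
  uint64_t nrec = get_u64(f);
  int nb = (k + 3) / 4;
  CharacterVector kmers((R_xlen_t)nrec);
  NumericVector counts((R_xlen_t)nrec);
  std::vector<uint8_t> buf((size_t)nb);
  std::vector<int8_t> codes((size_t)k);
  for (uint64_t i = 0; i < nrec; ++i) {
    uint8_t cb[4];
    if ((int)std::fread(buf.data(), 1, (size_t)nb, f) != nb ||
        std::fread(cb, 1, 4, f) != 4) {
      std::fclose(f);
      stop("truncated record %d in count file", (int)i + 1);
    }
    kb::unpack_bytes(buf.data(), k, codes.data());
    kmers[(R_xlen_t)i] = kb::codes_to_string(codes.data(), k);
    counts[(R_xlen_t)i] = (double)((uint32_t)cb[0] | ((uint32_t)cb[1] << 8) |
                                   ((uint32_t)cb[2] << 16) |
                                   ((uint32_t)cb[3] << 24));
  }
  std::fclose(f);
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}
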