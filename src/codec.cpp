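#include "common.h"
using namespace Rcpp;

// [[Rcpp::export]]
RawVector cpp_encode(std::string seq) {
  if (seq.empty()) stop("cannot encode an empty sequence");
  std::vector<int8_t> codes = kb::to_codes(seq);
  for (size_t i = 0; i < codes.size(); ++i)
    if (codes[i] < 0)
      stop("invalid base '%s' at position %d (only A/C/G/T allowed)",
           std::string(1, seq[i]).c_str(), (int)(i + 1));
  std::vector<uint8_t> packed = kb::pack_bytes(codes.data(), (int)codes.size());
  RawVector out(packed.size());
  std::copy(packed.begin(), packed.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
std::string cpp_decode(RawVector packed, int len) {
  if (len < 0 || (int)packed.size() != (len + 3) / 4)
    stop("packed length does not match declared base length");
  std::vector<int8_t> codes((size_t)len);
  kb::unpack_bytes((const uint8_t*)RAW(packed), len, codes.data());
  return kb::codes_to_string(codes.data(), len);
}

// [[Rcpp::export]]
RawVector cpp_revcomp(RawVector packed, int len) {
  std::vector<int8_t> codes((size_t)len), rc((size_t)len);
  kb::unpack_bytes((const uint8_t*)RAW(packed), len, codes.data());
  kb::revcomp_codes(codes.data(), len, rc.data());
  std::vector<uint8_t> out = kb::pack_bytes(rc.data(), len);
  RawVector res(out.size());
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// [[Rcpp::export]]
RawVector cpp_canonical(RawVector packed, int len) {
  std::vector<int8_t> codes((size_t)len), canon((size_t)len);
  kb::unpack_bytes((const uint8_t*)RAW(packed), len, codes.data());
  kb::canonical_codes(codes.data(), len, canon.data());
  std::vector<uint8_t> out = kb::pack_bytes(canon.data(), len);
  RawVector res(out.size());
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// maximal ACGT substrings, uppercased
// [[Rcpp::export]]
CharacterVector cpp_fragments(std::string seq) {
  std::vector<int8_t> codes = kb::to_codes(seq);
  std::vector<kb::Fragment> fr = kb::fragments_of(codes);
  CharacterVector out(fr.size());
  for (size_t i = 0; i < fr.size(); ++i)
    out[i] = kb::codes_to_string(codes.data() + fr[i].start, fr[i].len);
  return out;
}
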