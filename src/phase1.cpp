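#include "common.h"
using namespace Rcpp;

// [[Rcpp::export]]
int cpp_assign_file(double rank, int F) {
  if (F < 1) stop("F must be >= 1");
  return (int)kb::assign_file64((uint32_t)rank, (uint64_t)F);
}

// stream one batch of read sequences into the F bin files; returns per-bin
// super-mer and k-mer counts contributed by this batch
// [[Rcpp::export]]
List cpp_phase1_chunk(CharacterVector seqs, int k, int m, IntegerVector ranks,
                      bool canonical, CharacterVector bin_paths, bool append) {
  int F = (int)bin_paths.size();
  std::vector<FILE*> files((size_t)F, nullptr);
  for (int f = 0; f < F; ++f) {
    files[f] = std::fopen(as<std::string>(bin_paths[f]).c_str(),
                          append ? "ab" : "wb");
    if (!files[f]) {
      for (int g = 0; g < f; ++g) std::fclose(files[g]);
      stop("cannot open temporary bin file '%s'",
           as<std::string>(bin_paths[f]).c_str());
    }
  }
  NumericVector n_kmers(F), n_supermers(F);
  std::vector<kb::SuperMer> sms;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int8_t> codes = kb::to_codes(s);
    std::vector<kb::Fragment> fr = kb::fragments_of(codes);
    for (size_t f = 0; f < fr.size(); ++f) {
      if (fr[f].len < k) continue;
      sms.clear();
      kb::decompose(codes.data() + fr[f].start, fr[f].len, k, m,
                    INTEGER(ranks), canonical, sms);
      for (size_t j = 0; j < sms.size(); ++j) {
        int fid = (int)kb::assign_file64(sms[j].rank, (uint64_t)F);
        kb::write_record(files[fid],
                         codes.data() + fr[f].start + sms[j].start,
                         sms[j].len, sms[j].rank);
        n_kmers[fid] += (double)(sms[j].len - k + 1);
        n_supermers[fid] += 1;
      }
    }
  }
  for (int f = 0; f < F; ++f) std::fclose(files[f]);
  return List::create(_["n_kmers"] = n_kmers, _["n_supermers"] = n_supermers);
}

// append standalone super-mer records (unit-level bin writer)
// [[Rcpp::export]]
void cpp_write_supermers(std::string path, CharacterVector supermers,
                         NumericVector ranks, bool append) {
  FILE* f = std::fopen(path.c_str(), append ? "ab" : "wb");
  if (!f) stop("cannot open bin file '%s' for writing", path.c_str());
  for (R_xlen_t i = 0; i < supermers.size(); ++i) {
    std::string s = as<std::string>(supermers[i]);
    std::vector<int8_t> codes = kb::to_codes(s);
    for (size_t j = 0; j < codes.size(); ++j)
      if (codes[j] < 0) { std::fclose(f); stop("non-ACGT base in super-mer"); }
    kb::write_record(f, codes.data(), (int)codes.size(), (uint32_t)ranks[i]);
  }
  std::fclose(f);
}

// [[Rcpp::export]]
List cpp_read_bin(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open bin file '%s' for reading", path.c_str());
  std::vector<std::string> sms;
  std::vector<double> ranks;
  std::vector<int8_t> codes;
  uint32_t rank;
  while (true) {
    bool ok;
    try {
      ok = kb::read_record(f, codes, rank);
    } catch (...) {
      std::fclose(f);
      stop("corrupt record %d in bin file '%s'", (int)sms.size() + 1,
           path.c_str());
    }
    if (!ok) break;
    sms.push_back(kb::codes_to_string(codes.data(), (int)codes.size()));
    ranks.push_back((double)rank);
  }
  std::fclose(f);
  return List::create(_["supermer"] = wrap(sms), _["rank"] = wrap(ranks));
}
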