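#include <Rcpp.h>
#include <string>
#include <unordered_map>
using namespace Rcpp;

// Brute-force dictionary counter, deliberately written at the character
// level (no bit packing, no shared helpers) so it can serve as an
// independent reference for the hash-table pipeline.

static char comp_char(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

// [[Rcpp::export]]
List cpp_oracle_count(CharacterVector seqs, int k, bool canonical) {
  if (k < 1) stop("k must be >= 1");
  std::unordered_map<std::string, double> tab;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) s[j] = (char)std::toupper(s[j]);
    size_t start = 0;
    while (start < s.size()) {
      size_t end = start;
      while (end < s.size() &&
             (s[end] == 'A' || s[end] == 'C' || s[end] == 'G' || s[end] == 'T'))
        ++end;
      if (end == start) { ++start; continue; }
      if ((int)(end - start) >= k) {
        for (size_t w = start; w + (size_t)k <= end; ++w) {
          std::string kmer = s.substr(w, (size_t)k);
          if (canonical) {
            std::string rc((size_t)k, 'N');
            for (int q = 0; q < k; ++q) rc[q] = comp_char(kmer[k - 1 - q]);
            if (rc < kmer) kmer = rc;
          }
          tab[kmer] += 1;
        }
      }
      start = end + 1;
    }
  }
  CharacterVector kmers(tab.size());
  NumericVector counts(tab.size());
  R_xlen_t i = 0;
  for (auto& kv : tab) {
    kmers[i] = kv.first;
    counts[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}
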