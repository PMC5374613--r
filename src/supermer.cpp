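#include "common.h"
using namespace Rcpp;

static void check_ranks(const IntegerVector& ranks, int m) {
  double expect = std::pow(4.0, m);
  if ((double)ranks.size() != expect)
    stop("rank table has %d entries but 4^%d = %.0f are required",
         (int)ranks.size(), m, expect);
}

// minimizer of a single k-mer: minimal m-mer occurrence under the rank
// table; in canonical mode the minimum is over the windows of the k-mer
// and of its reverse complement
// [[Rcpp::export]]
List cpp_minimizer_of(std::string kmer, int m, IntegerVector ranks,
                      bool canonical) {
  int k = (int)kmer.size();
  if (k < m) stop("k-mer length %d is smaller than m = %d", k, m);
  check_ranks(ranks, m);
  std::vector<int8_t> codes = kb::to_codes(kmer);
  for (int i = 0; i < k; ++i)
    if (codes[i] < 0) stop("k-mer contains a non-ACGT base");

  kb::MinOcc best{0, -1, 0};
  uint64_t mask = ((uint64_t)1 << (2 * m)) - 1;
  uint64_t v = 0, r = 0;
  for (int j = 0; j < m; ++j) {
    v = (v << 2) | (uint64_t)codes[j];
    r |= ((uint64_t)(3 - codes[j])) << (2 * j);
  }
  for (int j = 0; j <= k - m; ++j) {
    if (j > 0) {
      v = ((v << 2) | (uint64_t)codes[j + m - 1]) & mask;
      r = (r >> 2) | (((uint64_t)(3 - codes[j + m - 1])) << (2 * (m - 1)));
    }
    uint32_t fr = (uint32_t)ranks[v];
    if (best.pos < 0 || fr < best.rank) best = {fr, j, 0};
    if (canonical) {
      uint32_t rr = (uint32_t)ranks[r];
      if (rr < best.rank) best = {rr, j, 1};
    }
  }
  // reconstruct the winning m-mer string
  std::vector<int8_t> mm((size_t)m);
  if (best.strand == 0) {
    for (int j = 0; j < m; ++j) mm[j] = codes[best.pos + j];
  } else {
    kb::revcomp_codes(codes.data() + best.pos, m, mm.data());
  }
  return List::create(
      _["mmer"] = kb::codes_to_string(mm.data(), m),
      _["rank"] = (double)best.rank, _["pos"] = best.pos,
      _["strand"] = best.strand == 0 ? "+" : "-");
}

// [[Rcpp::export]]
DataFrame cpp_super_mers(std::string fragment, int k, int m,
                         IntegerVector ranks, bool canonical) {
  int L = (int)fragment.size();
  if (L < k) stop("fragment of length %d is shorter than k = %d", L, k);
  if (k < m) stop("k = %d is smaller than m = %d", k, m);
  check_ranks(ranks, m);
  std::vector<int8_t> codes = kb::to_codes(fragment);
  for (int i = 0; i < L; ++i)
    if (codes[i] < 0) stop("fragment contains a non-ACGT base");
  std::vector<kb::SuperMer> sms;
  kb::decompose(codes.data(), L, k, m, INTEGER(ranks), canonical, sms);
  CharacterVector bases(sms.size());
  NumericVector rank(sms.size());
  IntegerVector start(sms.size()), nk(sms.size());
  for (size_t i = 0; i < sms.size(); ++i) {
    bases[i] = kb::codes_to_string(codes.data() + sms[i].start, sms[i].len);
    rank[i] = (double)sms[i].rank;
    start[i] = sms[i].start;
    nk[i] = sms[i].len - k + 1;
  }
  return DataFrame::create(_["supermer"] = bases, _["rank"] = rank,
                           _["start"] = start, _["n_kmers"] = nk,
                           _["stringsAsFactors"] = false);
}

// m-mer occurrence counts over the first `sample_size` ACGT fragments
// [[Rcpp::export]]
NumericVector cpp_sample_frequencies(CharacterVector seqs, int m,
                                     double sample_size) {
  size_t tab_n = (size_t)1 << (2 * m);
  NumericVector out((R_xlen_t)tab_n);
  uint64_t mask = ((uint64_t)1 << (2 * m)) - 1;
  double seen = 0;
  for (R_xlen_t i = 0; i < seqs.size() && seen < sample_size; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int8_t> codes = kb::to_codes(s);
    std::vector<kb::Fragment> fr = kb::fragments_of(codes);
    for (size_t f = 0; f < fr.size() && seen < sample_size; ++f) {
      seen += 1;
      if (fr[f].len < m) continue;
      const int8_t* c = codes.data() + fr[f].start;
      uint64_t v = 0;
      for (int j = 0; j < m; ++j) v = (v << 2) | (uint64_t)c[j];
      out[(R_xlen_t)v] += 1;
      for (int j = 1; j <= fr[f].len - m; ++j) {
        v = ((v << 2) | (uint64_t)c[j + m - 1]) & mask;
        out[(R_xlen_t)v] += 1;
      }
    }
  }
  return out;
}

// ordering metrics: total super-mer count and, per minimizer rank, the
// number of distinct (optionally canonical) k-mers that share it
// [[Rcpp::export]]
List cpp_evaluate_ordering(CharacterVector seqs, int k, int m,
                           IntegerVector ranks, bool canonical) {
  check_ranks(ranks, m);
  double total_sms = 0;
  std::unordered_map<uint32_t, std::unordered_set<std::string>> per_min;
  std::vector<int8_t> canon((size_t)k);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int8_t> codes = kb::to_codes(s);
    std::vector<kb::Fragment> fr = kb::fragments_of(codes);
    for (size_t f = 0; f < fr.size(); ++f) {
      if (fr[f].len < k) continue;
      std::vector<kb::SuperMer> sms;
      kb::decompose(codes.data() + fr[f].start, fr[f].len, k, m,
                    INTEGER(ranks), canonical, sms);
      total_sms += (double)sms.size();
      for (size_t j = 0; j < sms.size(); ++j) {
        const int8_t* base = codes.data() + fr[f].start + sms[j].start;
        auto& set = per_min[sms[j].rank];
        for (int w = 0; w + k <= sms[j].len; ++w) {
          if (canonical) {
            kb::canonical_codes(base + w, k, canon.data());
            set.insert(kb::codes_to_string(canon.data(), k));
          } else {
            set.insert(kb::codes_to_string(base + w, k));
          }
        }
      }
    }
  }
  double maxd = 0;
  NumericVector rk(per_min.size()), nd(per_min.size());
  R_xlen_t i = 0;
  for (auto& kv : per_min) {
    rk[i] = (double)kv.first;
    nd[i] = (double)kv.second.size();
    if (nd[i] > maxd) maxd = nd[i];
    ++i;
  }
  return List::create(_["total_supermers"] = total_sms,
                      _["max_distinct_per_minimizer"] = maxd,
                      _["minimizer_rank"] = rk, _["n_distinct"] = nd);
}
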