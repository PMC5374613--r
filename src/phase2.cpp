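#include "common.h"
#include <unordered_map>
using namespace Rcpp;

namespace {

struct CountTable {
  int k, nwords, imax;
  uint64_t capacity, inserted;
  uint64_t probe_ops, insert_ops;
  std::vector<uint64_t> keys;    // capacity * nwords
  std::vector<uint32_t> counts;  // 0 marks an empty slot

  CountTable(int k_, uint64_t cap, int imax_)
      : k(k_), nwords(kb::nwords_for(k_)), imax(imax_), capacity(cap),
        inserted(0), probe_ops(0), insert_ops(0),
        keys(cap * (uint64_t)kb::nwords_for(k_), 0), counts(cap, 0) {
    if (cap < 1) Rcpp::stop("table capacity must be >= 1");
  }

  bool key_equal(uint64_t idx, const uint64_t* key) const {
    const uint64_t* slot = keys.data() + idx * (uint64_t)nwords;
    for (int w = 0; w < nwords; ++w)
      if (slot[w] != key[w]) return false;
    return true;
  }

  // returns true if counted (new slot claimed or counter bumped),
  // false if the probe cap i_max was exhausted
  bool insert(const uint64_t* key) {
    insert_ops++;
    uint64_t h0 = kb::probe_hash64(key, k);
    for (int i = 0; i < imax; ++i) {
      uint64_t idx = kb::probe_slot(h0, (uint64_t)i, capacity);
      if (counts[idx] == 0) {
        uint64_t* slot = keys.data() + idx * (uint64_t)nwords;
        for (int w = 0; w < nwords; ++w) slot[w] = key[w];
        counts[idx] = 1;
        inserted++;
        probe_ops += (uint64_t)i + 1;
        return true;
      }
      if (key_equal(idx, key)) {
        if (counts[idx] != UINT32_MAX) counts[idx]++;  // saturating
        probe_ops += (uint64_t)i + 1;
        return true;
      }
    }
    probe_ops += (uint64_t)imax;
    return false;
  }
};

}  // namespace

// --- exposed hash primitives --------------------------------------------

static std::vector<uint64_t> kmer_words(const std::string& kmer) {
  std::vector<int8_t> codes = kb::to_codes(kmer);
  for (size_t i = 0; i < codes.size(); ++i)
    if (codes[i] < 0) stop("k-mer contains a non-ACGT base");
  std::vector<uint64_t> words((size_t)kb::nwords_for((int)codes.size()));
  kb::pack_words(codes.data(), (int)codes.size(), words.data());
  return words;
}

// [[Rcpp::export]]
double cpp_probe_slot(std::string kmer, double i, double capacity) {
  if (capacity < 1) stop("capacity must be >= 1");
  std::vector<uint64_t> w = kmer_words(kmer);
  uint64_t h0 = kb::probe_hash64(w.data(), (int)kmer.size());
  return (double)kb::probe_slot(h0, (uint64_t)i, (uint64_t)capacity);
}

// [[Rcpp::export]]
int cpp_part_hash(std::string kmer) {
  std::vector<uint64_t> w = kmer_words(kmer);
  return (int)kb::part_hash16(w.data(), (int)kmer.size());
}

// --- count-table object ---------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_table_new(int k, double capacity, int i_max) {
  if (k < 1) stop("k must be >= 1");
  if (i_max < 0) stop("i_max must be >= 0");
  XPtr<CountTable> p(new CountTable(k, (uint64_t)capacity, i_max), true);
  return p;
}

// [[Rcpp::export]]
LogicalVector cpp_table_insert(SEXP tbl, CharacterVector kmers) {
  XPtr<CountTable> p(tbl);
  LogicalVector out(kmers.size());
  std::vector<uint64_t> words((size_t)p->nwords);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != p->k)
      stop("k-mer length %d does not match table k = %d", (int)s.size(), p->k);
    std::vector<int8_t> codes = kb::to_codes(s);
    for (int j = 0; j < p->k; ++j)
      if (codes[j] < 0) stop("k-mer contains a non-ACGT base");
    kb::pack_words(codes.data(), p->k, words.data());
    out[i] = p->insert(words.data());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_table_counts(SEXP tbl) {
  XPtr<CountTable> p(tbl);
  std::vector<std::string> kmers;
  std::vector<double> counts;
  kmers.reserve(p->inserted);
  counts.reserve(p->inserted);
  std::vector<int8_t> codes((size_t)p->k);
  for (uint64_t idx = 0; idx < p->capacity; ++idx) {
    if (p->counts[idx] == 0) continue;
    kb::unpack_words(p->keys.data() + idx * (uint64_t)p->nwords, p->k,
                     codes.data());
    kmers.push_back(kb::codes_to_string(codes.data(), p->k));
    counts.push_back((double)p->counts[idx]);
  }
  return List::create(_["kmer"] = wrap(kmers), _["count"] = wrap(counts));
}

// [[Rcpp::export]]
List cpp_table_stats(SEXP tbl) {
  XPtr<CountTable> p(tbl);
  return List::create(
      _["k"] = p->k, _["capacity"] = (double)p->capacity,
      _["i_max"] = p->imax, _["inserted"] = (double)p->inserted,
      _["fill"] = (double)p->inserted / (double)p->capacity,
      _["mean_probes"] = p->insert_ops == 0
                             ? NA_REAL
                             : (double)p->probe_ops / (double)p->insert_ops);
}

// --- per-bin counting ------------------------------------------------------

// drain a failure buffer: recount spilled single k-mers in a dedicated
// table sized to the spill, growing x2 (with i_max doubled) on repeated
// failure so the loop always terminates
static void drain_failures(std::vector<uint64_t>& spill, int k, int nwords,
                           double beta, int imax,
                           std::vector<CountTable*>& tables,
                           double& drain_rounds) {
  uint64_t cap =
      kb::round_pow2((uint64_t)std::ceil((double)(spill.size() / nwords) / beta) + 1);
  int im = imax < 1 ? 1 : imax;
  while (!spill.empty()) {
    drain_rounds += 1;
    CountTable* t = new CountTable(k, cap, im);
    std::vector<uint64_t> next;
    for (size_t off = 0; off < spill.size(); off += (size_t)nwords) {
      if (!t->insert(spill.data() + off))
        next.insert(next.end(), spill.begin() + off,
                    spill.begin() + off + nwords);
    }
    tables.push_back(t);
    spill.swap(next);
    cap *= 2;
    im *= 2;
  }
}

// count all k-mers of one bin file: multi-pass selection by partition
// hash, sharded tables, bounded probing with failure buffers
// [[Rcpp::export]]
List cpp_count_bin(std::string path, double n_manifest, int k, bool canonical,
                   double alpha, double beta, int i_max, double t_max,
                   int n_shards) {
  if (k < 1) stop("k must be >= 1");
  if (i_max < 1) stop("i_max must be >= 1 for bin counting");
  if (n_shards < 1) stop("shard count must be >= 1");
  if (t_max < 1) stop("t_max must be >= 1");
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)");
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]");

  // load super-mer records
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open bin file '%s'", path.c_str());
  std::vector<int8_t> all_codes;
  std::vector<int> offsets, lens;
  {
    std::vector<int8_t> codes;
    uint32_t rank;
    int rec = 0;
    while (true) {
      bool ok;
      try {
        ok = kb::read_record(f, codes, rank);
      } catch (...) {
        std::fclose(f);
        stop("corrupt record %d in bin file '%s'", rec + 1, path.c_str());
      }
      if (!ok) break;
      ++rec;
      offsets.push_back((int)all_codes.size());
      lens.push_back((int)codes.size());
      all_codes.insert(all_codes.end(), codes.begin(), codes.end());
    }
  }
  std::fclose(f);

  double n = n_manifest;
  int p = (int)std::ceil(n / t_max);
  if (p < 1) p = 1;
  int nwords = kb::nwords_for(k);
  int N = n_shards;

  std::unordered_map<std::string, double> result;
  double total_counted = 0, spilled_total = 0, drain_rounds = 0;
  double probe_ops = 0, insert_ops = 0;
  double cap_total = 0;

  std::vector<int8_t> canon((size_t)k);
  std::vector<uint64_t> words((size_t)nwords);

  for (int pass = 0; pass < p; ++pass) {
    // per-shard tables sized from the running alpha estimate
    std::vector<CountTable*> tables;
    double n_exp = alpha * n / ((double)p * (double)N) / beta;
    uint64_t cap = kb::round_pow2((uint64_t)std::ceil(n_exp) + 1);
    for (int s = 0; s < N; ++s) tables.push_back(new CountTable(k, cap, i_max));
    cap_total += (double)cap * N;

    std::vector<std::vector<uint64_t>> spills((size_t)N);

    for (size_t r = 0; r < offsets.size(); ++r) {
      const int8_t* base = all_codes.data() + offsets[r];
      int L = lens[r];
      for (int w = 0; w + k <= L; ++w) {
        const int8_t* src = base + w;
        if (canonical) {
          kb::canonical_codes(src, k, canon.data());
          src = canon.data();
        }
        kb::pack_words(src, k, words.data());
        uint32_t ph = kb::part_hash16(words.data(), k);
        if ((int)(ph % (uint32_t)p) != pass) continue;
        int shard = (int)(ph % (uint32_t)N);
        if (!tables[shard]->insert(words.data())) {
          spills[shard].insert(spills[shard].end(), words.begin(), words.end());
          spilled_total += 1;
        }
      }
    }

    for (int s = 0; s < N; ++s)
      if (!spills[s].empty())
        drain_failures(spills[s], k, nwords, beta, i_max, tables, drain_rounds);

    // harvest this pass
    std::vector<int8_t> codes((size_t)k);
    for (size_t t = 0; t < tables.size(); ++t) {
      CountTable* tab = tables[t];
      probe_ops += (double)tab->probe_ops;
      insert_ops += (double)tab->insert_ops;
      for (uint64_t idx = 0; idx < tab->capacity; ++idx) {
        if (tab->counts[idx] == 0) continue;
        kb::unpack_words(tab->keys.data() + idx * (uint64_t)tab->nwords, k,
                         codes.data());
        result[kb::codes_to_string(codes.data(), k)] +=
            (double)tab->counts[idx];
        total_counted += (double)tab->counts[idx];
      }
      delete tab;
    }
  }

  CharacterVector kmers(result.size());
  NumericVector counts(result.size());
  R_xlen_t i = 0;
  for (auto& kv : result) {
    kmers[i] = kv.first;
    counts[i] = kv.second;
    ++i;
  }
  return List::create(
      _["kmer"] = kmers, _["count"] = counts,
      _["stats"] = List::create(
          _["n"] = n, _["distinct"] = (double)result.size(),
          _["total"] = total_counted, _["passes"] = p,
          _["spilled"] = spilled_total, _["drain_rounds"] = drain_rounds,
          _["mean_probes"] =
              insert_ops == 0 ? NA_REAL : probe_ops / insert_ops,
          _["capacity_total"] = cap_total));
}
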