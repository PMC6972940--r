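#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit packed canonical k-mer machinery, k <= 31 so a k-mer fits in 62 bits
// with the first base in the most-significant position (preserves
// lexicographic order of the ACGT alphabet under integer comparison).

typedef std::unordered_map<uint64_t, int> KmerMap;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t revcomp_packed(uint64_t x, int k) {
  uint64_t y = 0;
  for (int i = 0; i < k; ++i) {
    y = (y << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return y;
}

static inline uint64_t canonical(uint64_t x, int k) {
  uint64_t rc = revcomp_packed(x, k);
  return x < rc ? x : rc;
}

// Walk a sequence emitting packed k-mers; windows containing a non-ACGT
// symbol are skipped. `fn` is called with the canonical form.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F fn) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int valid = 0; // number of consecutive valid bases ending here
  const int n = (int) s.size();
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t) c) & mask;
    if (++valid >= k) fn(i - k + 1, canonical(cur, k));
  }
}

static void check_k(int k) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
}

// [[Rcpp::export(name = ".cm_kmer_table")]]
SEXP cm_kmer_table(CharacterVector seqs, int k) {
  check_k(k);
  KmerMap* m = new KmerMap();
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    for_each_kmer(s, k, [&](int, uint64_t km) { (*m)[km]++; });
  }
  XPtr<KmerMap> p(m, true);
  return p;
}

// [[Rcpp::export(name = ".cm_kmer_table_size")]]
double cm_kmer_table_size(SEXP ptr) {
  XPtr<KmerMap> p(ptr);
  return (double) p->size();
}

// [[Rcpp::export(name = ".cm_kmer_total")]]
double cm_kmer_total(SEXP ptr) {
  XPtr<KmerMap> p(ptr);
  double tot = 0;
  for (auto& kv : *p) tot += kv.second;
  return tot;
}

// [[Rcpp::export(name = ".cm_kmer_lookup")]]
IntegerVector cm_kmer_lookup(SEXP ptr, CharacterVector kmers, int k) {
  check_k(k);
  XPtr<KmerMap> p(ptr);
  IntegerVector out(kmers.size());
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    std::string s = as<std::string>(kmers[j]);
    if ((int) s.size() != k) { out[j] = NA_INTEGER; continue; }
    uint64_t cur = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { ok = false; break; }
      cur = (cur << 2) | (uint64_t) c;
    }
    if (!ok) { out[j] = NA_INTEGER; continue; }
    auto it = p->find(canonical(cur, k));
    out[j] = (it == p->end()) ? 0 : it->second;
  }
  return out;
}

static std::string decode_kmer(uint64_t x, int k) {
  static const char* b = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = b[x & 3ULL]; x >>= 2; }
  return s;
}

// [[Rcpp::export(name = ".cm_kmer_dump")]]
List cm_kmer_dump(SEXP ptr, int k) {
  XPtr<KmerMap> p(ptr);
  R_xlen_t n = (R_xlen_t) p->size();
  CharacterVector keys(n);
  IntegerVector counts(n);
  R_xlen_t j = 0;
  for (auto& kv : *p) {
    keys[j] = decode_kmer(kv.first, k);
    counts[j] = kv.second;
    ++j;
  }
  return List::create(_["kmer"] = keys, _["count"] = counts);
}

// Per-window counts along one sequence (NA where the window is skipped).
// [[Rcpp::export(name = ".cm_window_counts")]]
IntegerVector cm_window_counts(std::string s, SEXP ptr, int k) {
  check_k(k);
  XPtr<KmerMap> p(ptr);
  int nwin = std::max(0, (int) s.size() - k + 1);
  IntegerVector out(nwin, NA_INTEGER);
  for_each_kmer(s, k, [&](int pos, uint64_t km) {
    auto it = p->find(km);
    out[pos] = (it == p->end()) ? 0 : it->second;
  });
  return out;
}

// Replace with 'N' every base covered by a window whose canonical count
// exceeds max_freq. Sequences shorter than k pass through unchanged.
// [[Rcpp::export(name = ".cm_mask_seqs")]]
CharacterVector cm_mask_seqs(CharacterVector seqs, SEXP ptr, int k, int max_freq) {
  check_k(k);
  XPtr<KmerMap> p(ptr);
  CharacterVector out(seqs.size());
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    const int n = (int) s.size();
    if (n >= k) {
      std::vector<int> diff(n + 1, 0);
      for_each_kmer(s, k, [&](int pos, uint64_t km) {
        auto it = p->find(km);
        if (it != p->end() && it->second > max_freq) {
          diff[pos] += 1;
          diff[pos + k] -= 1;
        }
      });
      int cov = 0;
      for (int i = 0; i < n; ++i) {
        cov += diff[i];
        if (cov > 0) s[i] = 'N';
      }
    }
    out[j] = s;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}
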