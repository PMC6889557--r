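#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit encoding follows alphabetical order (A<C<G<T), so comparing encoded
// k-mers is equivalent to lexicographic comparison of the strings.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Emit the canonical form of every valid window of length k in seq.
// Windows containing any non-ACGT symbol are skipped entirely.
static void emit_canonical(const std::string& seq, int k,
                           std::vector<std::string>& out) {
  const int n = (int) seq.size();
  if (k < 1 || n < k) return;
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  std::string fwd(k, 'A'), rev(k, 'A');
  for (int i = 0; i + k <= n; ++i) {
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      if (code[i + j] < 0) { ok = false; break; }
    }
    if (!ok) continue;
    for (int j = 0; j < k; ++j) {
      int c = code[i + j];
      fwd[j] = BASES[c];
      rev[k - 1 - j] = BASES[3 - c];
    }
    out.push_back(fwd <= rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector seqs, int k,
                                    bool unique_only = true) {
  std::vector<std::string> all;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (CharacterVector::is_na(seqs[s])) continue;
    emit_canonical(as<std::string>(seqs[s]), k, all);
  }
  if (!unique_only) return wrap(all);
  std::unordered_set<std::string> seen;
  std::vector<std::string> uniq;
  uniq.reserve(all.size());
  for (const std::string& s : all) {
    if (seen.insert(s).second) uniq.push_back(s);
  }
  return wrap(uniq);
}

// Multiplicity table of canonical k-mers over all input sequences.
// [[Rcpp::export]]
IntegerVector cpp_kmer_counts(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> counts;
  std::vector<std::string> buf;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (CharacterVector::is_na(seqs[s])) continue;
    buf.clear();
    emit_canonical(as<std::string>(seqs[s]), k, buf);
    for (const std::string& km : buf) ++counts[km];
  }
  IntegerVector out(counts.size());
  CharacterVector nm(counts.size());
  R_xlen_t i = 0;
  for (const auto& kv : counts) {
    nm[i] = kv.first;
    out[i] = kv.second;
    ++i;
  }
  out.attr("names") = nm;
  return out;
}

// FNV-1a 64-bit hash, truncated to the top 53 bits so every value is exactly
// representable as an R double. Fixed offset basis/prime: sketches built on
// different machines are comparable.
// [[Rcpp::export]]
NumericVector cpp_hash53(CharacterVector x) {
  const uint64_t prime = 1099511628211ULL;
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_REAL; continue; }
    const char* s = x[i];
    uint64_t h = 14695981039346656037ULL;
    for (const char* p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= prime;
    }
    out[i] = (double)(h >> 11);
  }
  return out;
}
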