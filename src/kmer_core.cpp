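#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
#include <string>
#include "kmer_utils.h"
using namespace Rcpp;
using namespace kmerbeta;

// 2-bit packed canonical k-mer machinery. Encoding A=0, C=1, G=2, T=3 makes
// the numeric order of packed keys identical to the lexicographic order of
// the k-mer strings, so sorted key vectors double as lexicographically
// sorted spectra. k <= 31 keeps a k-mer inside one uint64.

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  int8_t code[256];
  init_code(code);

  size_t total = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    R_xlen_t len = LENGTH(STRING_ELT(seqs, s));
    if (len >= k) total += (size_t)(len - k + 1);
  }
  std::vector<uint64_t> acc;
  acc.reserve(total);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP str = STRING_ELT(seqs, s);
    accumulate_kmers(CHAR(str), LENGTH(str), k, canonical, code, acc);
  }
  if (acc.empty()) stop("no k-mers: every window shorter than k or ambiguous");
  return rle_sorted(acc, k);
}

// build a spectrum from explicit k-mer strings and counts (constructor path)
// [[Rcpp::export]]
List cpp_build_spectrum(CharacterVector kmers, IntegerVector counts, int k,
                        bool canonical) {
  if (kmers.size() != counts.size()) stop("kmers and counts lengths differ");
  int8_t code[256];
  init_code(code);
  const int shift = 2 * (k - 1);
  std::vector<std::pair<uint64_t, int64_t>> pairs;
  pairs.reserve(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP str = STRING_ELT(kmers, i);
    if (LENGTH(str) != k) stop("k-mer of wrong length: %s", CHAR(str));
    if (counts[i] <= 0) stop("counts must be positive");
    const char *p = CHAR(str);
    uint64_t fwd = 0, rev = 0;
    for (int j = 0; j < k; ++j) {
      int c = code[(unsigned char)p[j]];
      if (c < 0) stop("non-ACGT base in k-mer: %s", CHAR(str));
      fwd = (fwd << 2) | (uint64_t)c;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    }
    pairs.push_back({canonical ? std::min(fwd, rev) : fwd, counts[i]});
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<uint64_t> keys;
  std::vector<int> cnts;
  size_t i = 0;
  while (i < pairs.size()) {
    size_t j = i;
    int64_t tot = 0;
    while (j < pairs.size() && pairs[j].first == pairs[i].first)
      tot += pairs[j++].second;
    keys.push_back(pairs[i].first);
    cnts.push_back((int)std::min<int64_t>(tot, INT32_MAX));
    i = j;
  }
  return keys_counts_to_list(keys, cnts);
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(RawVector keys, int k) {
  static const char base[4] = {'A', 'C', 'G', 'T'};
  const uint64_t *kp = key_ptr(keys);
  R_xlen_t n = keys.size() / 8;
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t key = kp[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = base[key & 3];
      key >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
bool cpp_keys_sorted_unique(RawVector keys) {
  const uint64_t *kp = key_ptr(keys);
  R_xlen_t n = keys.size() / 8;
  for (R_xlen_t i = 1; i < n; ++i)
    if (kp[i - 1] >= kp[i]) return false;
  return true;
}

// Merge two sorted spectra; returns the sufficient statistics for both
// Bray-Curtis (sum of per-k-mer minimum counts) and presence/absence
// Jaccard (shared and union distinct-k-mer counts).
// [[Rcpp::export]]
NumericVector cpp_pair_stats(RawVector ka, IntegerVector ca,
                             RawVector kb, IntegerVector cb) {
  const uint64_t *ap = key_ptr(ka), *bp = key_ptr(kb);
  const int *cap = INTEGER(ca), *cbp = INTEGER(cb);
  R_xlen_t na = ka.size() / 8, nb = kb.size() / 8;
  R_xlen_t i = 0, j = 0;
  double sum_min = 0, shared = 0, uni = 0;
  while (i < na && j < nb) {
    uint64_t a = ap[i], b = bp[j];
    if (a == b) {
      sum_min += std::min(cap[i], cbp[j]);
      ++shared; ++uni; ++i; ++j;
    } else if (a < b) { ++uni; ++i; }
    else { ++uni; ++j; }
  }
  uni += (na - i) + (nb - j);
  return NumericVector::create(_["sum_min"] = sum_min,
                               _["n_shared"] = shared,
                               _["n_union"] = uni);
}

// filter by abundance band; used by filterSpectrum
// [[Rcpp::export]]
List cpp_filter_counts(RawVector keys, IntegerVector counts, int min_ab,
                       double max_ab) {
  const uint64_t *kp = key_ptr(keys);
  R_xlen_t n = keys.size() / 8;
  std::vector<uint64_t> k2;
  std::vector<int> c2;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (counts[i] >= min_ab && (double)counts[i] <= max_ab) {
      k2.push_back(kp[i]);
      c2.push_back(counts[i]);
    }
  }
  return keys_counts_to_list(k2, c2);
}
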