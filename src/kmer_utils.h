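#ifndef KMERBETA_KMER_UTILS_H
#define KMERBETA_KMER_UTILS_H

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <algorithm>

namespace kmerbeta {

inline const uint64_t *key_ptr(const Rcpp::RawVector &raw) {
  return reinterpret_cast<const uint64_t *>(RAW(raw));
}

// LSD byte radix sort restricted to the low `bytes` significant bytes
// (a k-mer occupies 2k bits); much faster than comparison sort on the
// tens of millions of windows a deep sample produces
inline void radix_sort_u64(std::vector<uint64_t> &v, int bytes) {
  const size_t n = v.size();
  if (n < 2) return;
  std::vector<uint64_t> buf(n);
  uint64_t *src = v.data(), *dst = buf.data();
  for (int b = 0; b < bytes; ++b) {
    size_t cnt[256] = {0};
    const int shift = 8 * b;
    for (size_t i = 0; i < n; ++i) ++cnt[(src[i] >> shift) & 0xFF];
    size_t pos = 0;
    size_t idx[256];
    for (int c = 0; c < 256; ++c) { idx[c] = pos; pos += cnt[c]; }
    for (size_t i = 0; i < n; ++i) dst[idx[(src[i] >> shift) & 0xFF]++] = src[i];
    std::swap(src, dst);
  }
  if (src != v.data())
    std::memcpy(v.data(), src, n * sizeof(uint64_t));
}

inline Rcpp::List keys_counts_to_list(const std::vector<uint64_t> &keys,
                                      const std::vector<int> &counts) {
  R_xlen_t n = (R_xlen_t)keys.size();
  Rcpp::RawVector rkeys(8 * n);
  if (n > 0) std::memcpy(RAW(rkeys), keys.data(), 8 * (size_t)n);
  Rcpp::IntegerVector rcounts(counts.begin(), counts.end());
  return Rcpp::List::create(Rcpp::_["keys"] = rkeys,
                            Rcpp::_["counts"] = rcounts);
}

// sort accumulated window keys (2k significant bits) and run-length encode
inline Rcpp::List rle_sorted(std::vector<uint64_t> &acc, int k) {
  radix_sort_u64(acc, (2 * k + 7) / 8);
  std::vector<uint64_t> keys;
  std::vector<int> counts;
  size_t i = 0, n = acc.size();
  while (i < n) {
    size_t j = i + 1;
    while (j < n && acc[j] == acc[i]) ++j;
    keys.push_back(acc[i]);
    counts.push_back((int)std::min<size_t>(j - i, INT32_MAX));
    i = j;
  }
  return keys_counts_to_list(keys, counts);
}

inline void init_code(int8_t *code) {
  for (int i = 0; i < 256; ++i) code[i] = -1;
  code[(unsigned char)'A'] = 0; code[(unsigned char)'a'] = 0;
  code[(unsigned char)'C'] = 1; code[(unsigned char)'c'] = 1;
  code[(unsigned char)'G'] = 2; code[(unsigned char)'g'] = 2;
  code[(unsigned char)'T'] = 3; code[(unsigned char)'t'] = 3;
}

// push the canonical k-mers of s[0..len) onto acc
inline void accumulate_kmers(const char *s, R_xlen_t len, int k,
                             bool canonical, const int8_t *code,
                             std::vector<uint64_t> &acc) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < len; ++i) {
    int c = code[(unsigned char)s[i]];
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) acc.push_back(canonical ? std::min(fwd, rev) : fwd);
  }
}

} // namespace kmerbeta

#endif
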