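#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
#include "rng.h"
#include "kmer_utils.h"
using namespace Rcpp;
using kmerbeta::hash_kmer;
using kmerbeta::key_ptr;

// bottom-s sketch: hash every distinct canonical k-mer with a seeded 64-bit
// mixer, keep the s smallest hash values together with their counts
// [[Rcpp::export]]
List cpp_sketch(RawVector keys, IntegerVector counts, double s, double seed) {
  R_xlen_t n = keys.size() / 8;
  const uint64_t *kp = key_ptr(keys);
  std::vector<std::pair<uint64_t, int>> hv(n);
  for (R_xlen_t i = 0; i < n; ++i)
    hv[i] = {hash_kmer(kp[i], (uint64_t)seed), counts[i]};
  R_xlen_t keep = (R_xlen_t)std::min((double)n, s);
  if (keep < n)
    std::nth_element(hv.begin(), hv.begin() + keep, hv.end());
  hv.resize(keep);
  std::sort(hv.begin(), hv.end());
  for (R_xlen_t i = 1; i < keep; ++i)
    if (hv[i].first == hv[i - 1].first)
      stop("64-bit hash collision in sketch; use a different hash seed");
  RawVector rh(8 * keep);
  IntegerVector rc(keep);
  for (R_xlen_t i = 0; i < keep; ++i) {
    std::memcpy(RAW(rh) + 8 * i, &hv[i].first, 8);
    rc[i] = hv[i].second;
  }
  return List::create(_["hashes"] = rh, _["counts"] = rc);
}

// Merged bottom-m statistics (Mash-style): walk the union of the two hash
// lists in ascending order, stop after m = min(s, |union|) entries, and
// accumulate shared count, sum of minimum counts, and each sample's count
// mass inside the merged bottom-m window.
// [[Rcpp::export]]
NumericVector cpp_sketch_pair_stats(RawVector ha, IntegerVector ca,
                                    RawVector hb, IntegerVector cb,
                                    double s) {
  R_xlen_t na = ha.size() / 8, nb = hb.size() / 8;
  const uint64_t *hap = key_ptr(ha), *hbp = key_ptr(hb);
  R_xlen_t i = 0, j = 0;
  double m = 0, shared = 0, sum_min = 0, ta = 0, tb = 0;
  while ((i < na || j < nb) && m < s) {
    if (i < na && j < nb) {
      uint64_t a = hap[i], b = hbp[j];
      if (a == b) {
        shared += 1; sum_min += std::min(ca[i], cb[j]);
        ta += ca[i]; tb += cb[j];
        ++i; ++j;
      } else if (a < b) { ta += ca[i]; ++i; }
      else { tb += cb[j]; ++j; }
    } else if (i < na) { ta += ca[i]; ++i; }
    else { tb += cb[j]; ++j; }
    m += 1;
  }
  return NumericVector::create(_["m"] = m, _["n_shared"] = shared,
                               _["sum_min"] = sum_min,
                               _["total_a"] = ta, _["total_b"] = tb);
}
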