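#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include "rng.h"
#include "kmer_utils.h"
using namespace Rcpp;
using kmerbeta::Xoshiro256pp;

// Paired-end read simulator. Fragment starts are uniform on the (linear)
// source genome, both strands equally likely; R1 reads the 5' end of the
// template strand, R2 the reverse complement of its 3' end. Substitutions
// occur independently per base with probability ramping linearly from
// err0 (cycle 1) to err1 (last cycle); the substituted base is uniform
// over the three alternatives. Indels are not modeled.

static inline char comp(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

namespace {

// one read pair per call; shared by the string-returning and the fused
// simulate-and-count paths so both consume the identical RNG stream
class PairGenerator {
  const CharacterVector &genomes;
  const int read_len;
  const double insert_mean, insert_sd;
  std::vector<double> perr;
  Xoshiro256pp rng;
public:
  PairGenerator(const CharacterVector &genomes_, int read_len_,
                double insert_mean_, double insert_sd_, double err0,
                double err1, double seed)
      : genomes(genomes_), read_len(read_len_), insert_mean(insert_mean_),
        insert_sd(insert_sd_), perr(read_len_), rng((uint64_t)seed) {
    for (int i = 0; i < read_len; ++i)
      perr[i] = read_len == 1
                    ? err0
                    : err0 + (err1 - err0) * (double)i / (read_len - 1);
  }
  void next(int taxon0, std::string &b1, std::string &b2) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    SEXP gs = STRING_ELT(genomes, taxon0);
    const char *g = CHAR(gs);
    long glen = LENGTH(gs);

    long frag = (long)std::llround(insert_mean + insert_sd * rng.normal());
    if (frag < read_len) frag = read_len;
    if (frag > glen) frag = glen;
    long start = (long)rng.unif_int((uint64_t)(glen - frag + 1));
    bool fwd = (rng.next() & 1ULL) == 0ULL;

    if (fwd) {
      for (int i = 0; i < read_len; ++i) b1[i] = g[start + i];
      for (int i = 0; i < read_len; ++i) b2[i] = comp(g[start + frag - 1 - i]);
    } else {
      // template is the reverse-complement strand of the fragment
      for (int i = 0; i < read_len; ++i) b1[i] = comp(g[start + frag - 1 - i]);
      for (int i = 0; i < read_len; ++i) b2[i] = g[start + i];
    }
    for (int i = 0; i < read_len; ++i) {
      if (perr[i] > 0 && rng.unif() < perr[i]) {
        int orig = (b1[i] == 'A') ? 0 : (b1[i] == 'C') ? 1
                   : (b1[i] == 'G') ? 2 : 3;
        b1[i] = bases[(orig + 1 + (int)rng.unif_int(3)) & 3];
      }
      if (perr[i] > 0 && rng.unif() < perr[i]) {
        int orig = (b2[i] == 'A') ? 0 : (b2[i] == 'C') ? 1
                   : (b2[i] == 'G') ? 2 : 3;
        b2[i] = bases[(orig + 1 + (int)rng.unif_int(3)) & 3];
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_simulate_pairs(CharacterVector genomes, IntegerVector taxon_idx,
                        int read_len, double insert_mean, double insert_sd,
                        double err0, double err1, double seed) {
  R_xlen_t n_pairs = taxon_idx.size();
  PairGenerator gen(genomes, read_len, insert_mean, insert_sd, err0, err1,
                    seed);
  CharacterVector r1(n_pairs), r2(n_pairs);
  std::string b1(read_len, 'N'), b2(read_len, 'N');
  for (R_xlen_t p = 0; p < n_pairs; ++p) {
    gen.next(taxon_idx[p] - 1, b1, b2);
    r1[p] = b1;
    r2[p] = b2;
  }
  return List::create(_["r1"] = r1, _["r2"] = r2);
}

// fused fast path for the experiment runner: simulate the same reads as
// cpp_simulate_pairs (identical RNG stream) but accumulate their canonical
// k-mers directly instead of materializing read strings
// [[Rcpp::export]]
List cpp_simulate_count(CharacterVector genomes, IntegerVector taxon_idx,
                        int read_len, double insert_mean, double insert_sd,
                        double err0, double err1, double seed, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  R_xlen_t n_pairs = taxon_idx.size();
  PairGenerator gen(genomes, read_len, insert_mean, insert_sd, err0, err1,
                    seed);
  int8_t code[256];
  kmerbeta::init_code(code);
  std::vector<uint64_t> acc;
  if (read_len >= k)
    acc.reserve(2 * (size_t)n_pairs * (size_t)(read_len - k + 1));
  std::string b1(read_len, 'N'), b2(read_len, 'N');
  for (R_xlen_t p = 0; p < n_pairs; ++p) {
    gen.next(taxon_idx[p] - 1, b1, b2);
    kmerbeta::accumulate_kmers(b1.data(), read_len, k, true, code, acc);
    kmerbeta::accumulate_kmers(b2.data(), read_len, k, true, code, acc);
  }
  if (acc.empty()) stop("no k-mers: read length shorter than k");
  return kmerbeta::rle_sorted(acc, k);
}
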