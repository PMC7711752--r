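#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3; -1 for anything else.
// Codes are returned to R as doubles, exact for 2k <= 52 bits (k <= 26).

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// splitmix64 finalizer; seedable by pre-mixing the seed into the key
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_code(uint64_t code, uint64_t seed) {
  return mix64(code ^ mix64(seed));
}

// Distinct canonical k-mers over all records; windows with non-ACGT skipped,
// k-mers never span record boundaries. Sorted ascending (== lexicographic
// order of the k-mer strings, since A<C<G<T matches 0<1<2<3).
// [[Rcpp::export]]
NumericVector kmer_codes_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  std::vector<uint64_t> out;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char *s = CHAR(seqs[i]);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (const char *p = s; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) out.push_back(fwd < rev ? fwd : rev);
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  NumericVector res(out.size());
  for (size_t j = 0; j < out.size(); ++j) res[j] = (double)out[j];
  return res;
}

// Size of the intersection of two sorted distinct numeric vectors.
// [[Rcpp::export]]
double intersect_size_cpp(NumericVector a, NumericVector b) {
  R_xlen_t i = 0, j = 0;
  double n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// Bottom-s sketch: the s smallest distinct 53-bit hash values of the codes.
// [[Rcpp::export]]
NumericVector minhash_cpp(NumericVector codes, int s, int seed) {
  if (s < 1) stop("sketch size s must be >= 1");
  std::vector<uint64_t> h(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    h[i] = hash_code((uint64_t)codes[i], (uint64_t)(int64_t)seed) >> 11; // 53 bits
  std::sort(h.begin(), h.end());
  h.erase(std::unique(h.begin(), h.end()), h.end());
  size_t n = std::min((size_t)s, h.size());
  NumericVector res(n);
  for (size_t j = 0; j < n; ++j) res[j] = (double)h[j];
  return res;
}

// HyperLogLog register fill: bucket = top p bits of a 64-bit hash, register
// value = 1 + number of leading zeros of the remaining 64-p bits.
// [[Rcpp::export]]
IntegerVector hll_registers_cpp(NumericVector codes, int p, int seed) {
  if (p < 4 || p > 24) stop("p must be between 4 and 24");
  const int m = 1 << p;
  IntegerVector reg(m); // zero-initialised
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t h = hash_code((uint64_t)codes[i], (uint64_t)(int64_t)seed);
    uint32_t bucket = (uint32_t)(h >> (64 - p));
    uint64_t rest = h << p;
    int rank = (rest == 0) ? (64 - p + 1) : (1 + __builtin_clzll(rest));
    if (rank > reg[bucket]) reg[bucket] = rank;
  }
  return reg;
}

// Decode 2-bit codes back to k-mer strings.
// [[Rcpp::export]]
CharacterVector decode_kmers_cpp(NumericVector codes, int k) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector res(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) { buf[j] = bases[c & 3ULL]; c >>= 2; }
    res[i] = buf;
  }
  return res;
}
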