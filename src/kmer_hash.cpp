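#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Hashes are masked to 53 bits so every value is exactly representable as an
// R double: sketches stay sortable, comparable and JSON-round-trippable.
static const uint64_t HASH_MASK = (1ULL << 53) - 1;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// FNV-1a over the bytes, seeded, with a splitmix64 finalizer for avalanche.
static inline uint64_t hash_bytes(const char* s, int n, uint64_t seed) {
  uint64_t h = 0xCBF29CE484222325ULL ^ splitmix64(seed);
  for (int i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 0x100000001B3ULL;
  }
  return splitmix64(h) & HASH_MASK;
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;  // invalid
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

//' Hash k-mer strings with the package hash
//'
//' Applies the package's seeded 53-bit hash to each string as given (no
//' canonicalization). Used by sketching internals and as the shared hash
//' primitive for independent brute-force checks.
//'
//' @param kmers character vector of k-mer strings (uppercase ACGT).
//' @param seed non-negative integer hash seed.
//' @return numeric vector of 53-bit hash values.
//' @export
// [[Rcpp::export]]
NumericVector hash_kmer(CharacterVector kmers, double seed) {
  uint64_t sd = (uint64_t)seed;
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    out[i] = (double)hash_bytes(s, (int)LENGTH(STRING_ELT(kmers, i)), sd);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector kmer_hash_set_cpp(std::string seq, int k, double seed) {
  uint64_t sd = (uint64_t)seed;
  int n = (int)seq.size();
  std::vector<double> hashes;
  if (n < k) return NumericVector(0);
  std::string rc(k, 'N');
  // last_bad: index of the most recent non-ACGT character seen
  int last_bad = -1;
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (!valid_base(c)) { last_bad = i; continue; }
    int start = i - k + 1;
    if (start < 0 || start <= last_bad) continue;
    const char* fwd = seq.data() + start;
    for (int j = 0; j < k; ++j) rc[j] = complement(fwd[k - 1 - j]);
    // canonical k-mer: lexicographic min of forward and reverse complement
    const char* canon = fwd;
    if (std::lexicographical_compare(rc.begin(), rc.end(), fwd, fwd + k))
      canon = rc.data();
    hashes.push_back((double)hash_bytes(canon, k, sd));
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  return wrap(hashes);
}
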