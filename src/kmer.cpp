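// Canonical k-mer machinery: 2-bit packed k-mers (k <= 31) in uint64, stored
// on the R side as bit-reinterpreted doubles. For k <= 31 a code occupies at
// most 62 bits, so the exponent field of the double is never all-ones and the
// payload can never alias NaN/Inf. R code must treat the doubles as opaque:
// every comparison/merge happens here, on the uint64 interpretation.
#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static inline uint64_t d2u(double d) { uint64_t u; std::memcpy(&u, &d, 8); return u; }
static inline double u2d(uint64_t u) { double d; std::memcpy(&d, &u, 8); return d; }

// A=0 C=1 G=2 T=3, case-insensitive; anything else (incl. N) = 4
static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}
static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// Streaming canonical k-mer emitter over one sequence; calls f(code) per k-mer
template <typename F>
static void for_each_canonical(const char* s, size_t n, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b == 4) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector sequences, int k) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  std::unordered_map<uint64_t, uint32_t> tab;
  for (R_xlen_t i = 0; i < sequences.size(); ++i) {
    const char* s = CHAR(STRING_ELT(sequences, i));
    for_each_canonical(s, std::strlen(s), k, [&](uint64_t c) { tab[c]++; });
  }
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector code(keys.size());
  IntegerVector count(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    code[i] = u2d(keys[i]);
    count[i] = (int)tab[keys[i]];
  }
  return List::create(_["code"] = code, _["count"] = count);
}

// counts in B for each (sorted) code of A; 0 where absent. Both inputs sorted
// by uint64 interpretation.
// [[Rcpp::export]]
IntegerVector cpp_lookup_counts(NumericVector codesA, NumericVector codesB,
                                IntegerVector countsB) {
  R_xlen_t na = codesA.size(), nb = codesB.size();
  IntegerVector out(na);
  R_xlen_t j = 0;
  for (R_xlen_t i = 0; i < na; ++i) {
    uint64_t a = d2u(codesA[i]);
    while (j < nb && d2u(codesB[j]) < a) ++j;
    out[i] = (j < nb && d2u(codesB[j]) == a) ? countsB[j] : 0;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = d2u(codes[i]);
    for (int p = k - 1; p >= 0; --p) { buf[p] = BITS2BASE[c & 3]; c >>= 2; }
    out[i] = buf;
  }
  return out;
}

// canonicalize + encode literal k-mer strings; invalid (wrong length or
// non-ACGT) yields NA
// [[Rcpp::export]]
NumericVector cpp_encode_kmers(CharacterVector kmers, int k) {
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)std::strlen(s) != k) { out[i] = NA_REAL; continue; }
    bool seen = false;
    uint64_t got = 0;
    for_each_canonical(s, k, k, [&](uint64_t c) { got = c; seen = true; });
    out[i] = seen ? u2d(got) : NA_REAL;
  }
  return out;
}

// 1-based start positions in seq whose canonical k-mer is in the sorted set;
// also returns the index (1-based) into the set for each hit.
// [[Rcpp::export]]
List cpp_scan_positions(std::string seq, NumericVector codes, int k) {
  std::vector<uint64_t> set(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) set[i] = d2u(codes[i]);
  std::vector<int> pos, idx;
  // re-walk with explicit position tracking
  const char* s = seq.c_str();
  size_t n = seq.size();
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b == 4) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) {
      uint64_t c = fwd < rev ? fwd : rev;
      auto it = std::lower_bound(set.begin(), set.end(), c);
      if (it != set.end() && *it == c) {
        pos.push_back((int)(i - k + 2)); // 1-based start
        idx.push_back((int)(it - set.begin()) + 1);
      }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["set_index"] = wrap(idx));
}

// per-read hit counts against two sorted marker sets (trio binning fast path)
// [[Rcpp::export]]
IntegerMatrix cpp_read_marker_hits(CharacterVector reads, NumericVector matCodes,
                                   NumericVector patCodes, int k) {
  std::vector<uint64_t> mat(matCodes.size()), pat(patCodes.size());
  for (R_xlen_t i = 0; i < matCodes.size(); ++i) mat[i] = d2u(matCodes[i]);
  for (R_xlen_t i = 0; i < patCodes.size(); ++i) pat[i] = d2u(patCodes[i]);
  IntegerMatrix out(reads.size(), 2);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int nm = 0, np = 0;
    for_each_canonical(s, std::strlen(s), k, [&](uint64_t c) {
      if (std::binary_search(mat.begin(), mat.end(), c)) ++nm;
      if (std::binary_search(pat.begin(), pat.end(), c)) ++np;
    });
    out(r, 0) = nm;
    out(r, 1) = np;
  }
  return out;
}
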