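#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// 64 bits of the packed sequence starting at bit position `pos`
static inline uint64_t get_bits(const std::vector<uint64_t>& w, int pos) {
  const int word = pos >> 6, off = pos & 63;
  uint64_t lo = w[word] >> off;
  if (off) lo |= w[word + 1] << (64 - off);
  return lo;
}

// Lempel-Ziv 1976 complexity of a binary sequence: the number of words in
// the exhaustive-history parsing (final incomplete word counted), as in the
// Kaspar-Schuster procedure. A word starting at l has length
// 1 + max_{i < l} LCP(s[i..], s[l..]) (self-overlapping matches allowed);
// the LCP is computed 64 bits at a time on the packed sequence.
// [[Rcpp::export]]
int lz76_count_cpp(const IntegerVector& s) {
  const int n = s.size();
  if (n < 2) stop("sequence must have length >= 2");
  std::vector<uint64_t> w(n / 64 + 2, 0ULL);
  for (int i = 0; i < n; ++i) if (s[i]) w[i >> 6] |= (1ULL << (i & 63));
  int c = 1;  // the first symbol is always a word
  int l = 1;
  while (l < n) {
    const int cap = n - l;  // a match cannot extend past the end
    int kmax = 0;
    for (int i = 0; i < l && kmax < cap; ++i) {
      int m = 0;
      while (m < cap) {
        const uint64_t x = get_bits(w, i + m) ^ get_bits(w, l + m);
        if (x == 0) m += 64;
        else { m += __builtin_ctzll(x); break; }
      }
      if (m > cap) m = cap;
      if (m > kmax) kmax = m;
    }
    ++c;
    if (kmax >= cap) break;  // word reproducible to the end: final word
    l += kmax + 1;
  }
  return c;
}
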