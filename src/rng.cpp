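#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based (stateless) pseudo-random stream built on the splitmix64
// finaliser. Each draw is a pure function of (seed, stream, index), so a
// field's draws for participant i never depend on how many participants
// precede or follow i, nor on which other fields were generated.

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
NumericVector cb_unif(double seed, double stream, NumericVector index) {
  R_xlen_t n = index.size();
  NumericVector out(n);
  // seed and stream are R doubles holding non-negative integers < 2^53
  uint64_t s = mix64((uint64_t)seed);
  uint64_t st = mix64(s ^ mix64((uint64_t)stream + 0x632BE59BD9B4E019ULL));
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t k = mix64(st ^ mix64((uint64_t)index[i]));
    // 53-bit mantissa, offset by half an ulp: strictly inside (0, 1)
    out[i] = ((double)(k >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  return out;
}
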