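#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// SplitMix64 finalizer: full-period 64-bit mixer with good avalanche
// properties; adequate as a stateless counter-based generator.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

//' Stateless counter-based uniform draws
//'
//' Hashes (seed, id, event, period, rep) into a double in (0, 1). Draws are
//' a pure function of the key, so two simulation runs that share a seed give
//' every individual identical event outcomes regardless of what else is in
//' the population (the common-random-numbers contract).
//'
//' @param seed integer-valued scalar seed.
//' @param id numeric vector of individual ids (integer-valued, may exceed
//'   32-bit range).
//' @param event integer event code.
//' @param period integer calendar period key.
//' @param rep numeric repetition index (scalar or one per id); distinguishes
//'   multiple draws for the same (id, event, period), e.g. multiple births.
//' @return numeric vector of uniforms strictly inside (0, 1).
//' @keywords internal
// [[Rcpp::export]]
NumericVector counter_uniform_cpp(double seed, NumericVector id, int event,
                                  int period, NumericVector rep) {
  R_xlen_t n = id.size();
  bool rep_scalar = (rep.size() == 1);
  if (!rep_scalar && rep.size() != n)
    stop("rep must be scalar or match length of id");
  NumericVector out(n);
  uint64_t s = splitmix64((uint64_t)(int64_t)seed ^ 0xA5A5A5A5A5A5A5A5ULL);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t h = splitmix64(s ^ (uint64_t)(int64_t)id[i]);
    h = splitmix64(h ^ (uint64_t)(int64_t)event);
    h = splitmix64(h ^ (uint64_t)(int64_t)period);
    double r = rep_scalar ? rep[0] : rep[i];
    h = splitmix64(h ^ (uint64_t)(int64_t)r);
    // 53 bits of mantissa, offset by half a ulp so 0 and 1 are excluded
    out[i] = ((double)(h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  return out;
}
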