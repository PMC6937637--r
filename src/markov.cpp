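// Order-m Markov chain sampler over {A,C,G,T}, used by the synthetic
// corpus generator. Contexts are coded base-4 with the oldest base most
// significant, so the update is ctx <- (4*ctx + b) mod 4^m. Uses R's
// RNG (seeded by the caller), so draws are reproducible per seed.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".markov_sample")]]
IntegerVector markov_sample(NumericMatrix trans, int order, int len) {
  int nctx = trans.nrow();
  if (trans.ncol() != 4) stop("transition table must have 4 columns");
  if (len < order + 1) stop("length must exceed the Markov order");
  IntegerVector out(len);
  int ctx = 0;
  for (int i = 0; i < order; ++i) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    out[i] = b;
    ctx = ctx * 4 + b;
  }
  for (int i = order; i < len; ++i) {
    double u = unif_rand(), acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(ctx, j);
      if (u <= acc) { b = j; break; }
    }
    out[i] = b;
    ctx = (ctx * 4 + b) % nctx;
  }
  return out;
}
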