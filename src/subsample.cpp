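#include <Rcpp.h>
using namespace Rcpp;

// Multivariate hypergeometric draw: sample `depth` reads without
// replacement from a population in which clonotype i contributes
// counts[i] indistinguishable reads. Sequential conditional hypergeometric
// draws via R's rhyper, so results are reproducible under R's RNG seed.
// [[Rcpp::export]]
IntegerVector mvhyper_draw(IntegerVector counts, int depth) {
  int n = counts.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (counts[i] < 0) stop("negative count");
    total += counts[i];
  }
  if (depth < 0 || depth > total) stop("depth out of range");
  IntegerVector out(n);
  double rem = total;
  int need = depth;
  for (int i = 0; i < n && need > 0; ++i) {
    double white = counts[i];
    double black = rem - white;
    int k = (black <= 0.0) ? need
                           : (int) R::rhyper(white, black, (double) need);
    out[i] = k;
    need -= k;
    rem -= white;
  }
  return out;
}
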