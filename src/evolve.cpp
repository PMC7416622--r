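#include <Rcpp.h>
using namespace Rcpp;

// Proposal-based codon sequence evolution: pick a uniform random site, propose
// a uniform random different base, reject proposals creating internal stop
// codons, accept synonymous proposals always and nonsynonymous ones with
// probability omega, until the NG86 synonymous-difference count against the
// branch parent reaches the supplied target (or the iteration cap is hit,
// which flags saturation). Uses R's RNG so results are reproducible under
// set.seed().
//
// codons: 1-based codon indices (A,C,G,T base-4 digits, weights 16/4/1)
// sdTab:  64x64 NG86 pathway-averaged synonymous difference counts (NA where
//         every pathway is blocked; such codon pairs contribute 0 here, they
//         are skipped by the downstream estimator as well)
// [[Rcpp::export(name = ".evolveCodonsCpp")]]
List evolveCodonsCpp(IntegerVector codons, double omega, double targetSd,
                     NumericMatrix sdTab, LogicalVector isStop,
                     IntegerVector aaCode, int maxIter) {
  int L = codons.size();
  IntegerVector cur = clone(codons);
  auto contrib = [&](int parent0, int cur0) {
    double v = sdTab(parent0, cur0);
    return NumericMatrix::is_na(v) ? 0.0 : v;
  };
  double sd = 0.0; // parent == start, all contributions zero
  int iter = 0, accepted = 0;
  const int w[3] = {16, 4, 1};
  while (sd < targetSd && iter < maxIter) {
    ++iter;
    int site = (int)(unif_rand() * (3.0 * L));
    if (site >= 3 * L) site = 3 * L - 1;
    int ci = site / 3, pos = site % 3;
    int c0 = cur[ci] - 1;
    int digit = (c0 / w[pos]) % 4;
    int r = (int)(unif_rand() * 3.0);
    if (r >= 3) r = 2;
    int nb = r < digit ? r : r + 1; // uniform over the 3 other bases
    int n0 = c0 + (nb - digit) * w[pos];
    if (isStop[n0]) continue;
    bool syn = aaCode[n0] == aaCode[c0];
    if (!syn && unif_rand() >= omega) continue;
    sd += contrib(codons[ci] - 1, n0) - contrib(codons[ci] - 1, c0);
    cur[ci] = n0 + 1;
    ++accepted;
  }
  return List::create(_["codons"] = cur, _["sd"] = sd,
                      _["iterations"] = iter, _["accepted"] = accepted,
                      _["capped"] = (sd < targetSd));
}
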