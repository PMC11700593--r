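#include <Rcpp.h>
using namespace Rcpp;

// Build one generation of gamete haplotypes.
//
// H:       sites x (2N) 0/1 haplotype matrix, sites sorted by (chrom, pos)
// chrom:   1-based chromosome index per site (non-decreasing)
// pos:     position per site (increasing within chromosome)
// parent:  1-based parent individual per gamete (length G); parent k owns
//          columns 2k-1 and 2k of H
// breaks:  per gamete, a list with one sorted numeric vector of crossover
//          positions per chromosome
// starts:  n_chrom x G 0/1 matrix: which parental haplotype each gamete
//          starts from at the left end of each chromosome
// [[Rcpp::export]]
IntegerMatrix wf_gametes(const IntegerMatrix& H, const IntegerVector& chrom,
                         const NumericVector& pos,
                         const IntegerVector& parent, const List& breaks,
                         const IntegerMatrix& starts) {
  const int S = H.nrow();
  const int G = parent.size();
  IntegerMatrix out(S, G);
  for (int g = 0; g < G; ++g) {
    const int a = 2 * (parent[g] - 1);
    const int b = a + 1;
    List bg = breaks[g];
    int cur_chrom = -1, bi = 0, hap = 0;
    NumericVector bk;
    for (int s = 0; s < S; ++s) {
      const int c = chrom[s] - 1;
      if (c != cur_chrom) {
        cur_chrom = c;
        bk = bg[c];
        bi = 0;
        hap = starts(c, g);
      }
      while (bi < bk.size() && pos[s] > bk[bi]) { hap ^= 1; ++bi; }
      out(s, g) = hap ? H(s, b) : H(s, a);
    }
  }
  return out;
}
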