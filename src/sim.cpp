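#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Draw one recombinant gamete per parental haplotype pair and stack
// two gametes per offspring.
//
// H:          haplotypes x SNPs matrix; individual i owns rows 2i-1, 2i
// p1, p2:     1-based parent individual indices per offspring
// chromFirst: 1-based first column of each chromosome
// chromLast:  1-based last column of each chromosome
// pos:        bp positions of all SNPs (sorted within chromosome)
// rate:       per-bp per-meiosis crossover probability
// chromLen:   chromosome length in bp
//
// Crossovers are Poisson(rate * chromLen) per chromosome, placed
// uniformly; the starting haplotype is chosen at random. Uses R's RNG
// stream, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix make_offspring_cpp(IntegerMatrix H, IntegerVector p1,
                                 IntegerVector p2,
                                 IntegerVector chromFirst,
                                 IntegerVector chromLast,
                                 NumericVector pos, double rate,
                                 double chromLen) {
  int nOff = p1.size();
  int S = H.ncol();
  int nChrom = chromFirst.size();
  IntegerMatrix out(2 * nOff, S);
  const int* Hp = INTEGER(H);
  int nrowH = H.nrow();
  int* Op = INTEGER(out);
  int nrowO = out.nrow();
  std::vector<double> breaks;

  for (int i = 0; i < nOff; i++) {
    for (int g = 0; g < 2; g++) {
      int parent = (g == 0) ? p1[i] : p2[i];
      int r1 = 2 * parent - 2;          // 0-based haplotype rows
      int r2 = 2 * parent - 1;
      int outRow = 2 * i + g;
      for (int c = 0; c < nChrom; c++) {
        int lo = chromFirst[c] - 1, hi = chromLast[c] - 1;
        int k = (int)R::rpois(rate * chromLen);
        int cur = (unif_rand() < 0.5) ? 0 : 1;
        if (k == 0) {
          int src = cur ? r2 : r1;
          for (int j = lo; j <= hi; j++)
            Op[(R_xlen_t)j * nrowO + outRow] = Hp[(R_xlen_t)j * nrowH + src];
        } else {
          breaks.resize(k);
          for (int b = 0; b < k; b++) breaks[b] = unif_rand() * chromLen;
          std::sort(breaks.begin(), breaks.end());
          int b = 0;
          int phase = cur;
          for (int j = lo; j <= hi; j++) {
            while (b < k && breaks[b] < pos[j]) { b++; phase ^= 1; }
            int src = phase ? r2 : r1;
            Op[(R_xlen_t)j * nrowO + outRow] = Hp[(R_xlen_t)j * nrowH + src];
          }
        }
      }
    }
  }
  return out;
}
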