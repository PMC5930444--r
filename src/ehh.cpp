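#include <Rcpp.h>
using namespace Rcpp;

// Extended-haplotype-homozygosity decay outward from a core SNP by
// successive class refinement.
//
// H:       haplotypes x SNPs 0/1 matrix (distinct haplotype patterns;
//          exact duplicates may be collapsed with multiplicities)
// core:    1-based core column
// lo,hi:   1-based inclusive column bounds of the core's chromosome
// dir:     +1 (right) or -1 (left)
// sets:    list of 1-based haplotype row index vectors; EHH is tracked
//          for each set
// weights: list of per-row multiplicities parallel to sets (total
//          weight of each set must be >= 2)
// stopSet: 1-based index of the set whose EHH governs truncation
// cutoff:  stop after recording the first step where the stop set's
//          EHH drops below this value
//
// EHH of a set at flank x = probability that two distinct haplotypes
// drawn from the (weighted) set are identical over (core..x], i.e.
// sum_k W_k (W_k - 1) / (W (W - 1)) over identity classes k.
//
// Classes reduced to a single pattern row can never split again; their
// contribution w (w - 1) is frozen and the row retires from
// refinement, so the per-step cost is proportional to the rows still
// in multi-pattern classes. When the stop set has no refinable rows
// left its EHH is constant to the chromosome end: if that plateau is
// still >= cutoff the decay can never truncate and the scan stops
// early, reporting stopped = FALSE.
//
// Returns idx (1-based flank columns visited, in order), ehh (steps x
// n_sets matrix) and stopped (TRUE iff the stop-set EHH fell below the
// cutoff before the chromosome end).
// [[Rcpp::export]]
List ehh_decay_cpp(IntegerMatrix H, int core, int lo, int hi, int dir,
                   List sets, List weights, int stopSet, double cutoff) {
  const int nset = sets.size();
  const int nrowH = H.nrow();
  const int* Hp = INTEGER(H);

  std::vector< std::vector<int> > rows(nset), grp(nset), act(nset);
  std::vector< std::vector<double> > w(nset);
  std::vector<double> totw(nset), frozen(nset, 0.0), lastEhh(nset, 1.0);
  std::vector< std::vector<int> > relab(nset);
  std::vector< std::vector<double> > cntW(nset);
  std::vector< std::vector<int> > cntN(nset);

  for (int s = 0; s < nset; s++) {
    IntegerVector rv = sets[s];
    NumericVector wv = weights[s];
    int ms = rv.size();
    rows[s].resize(ms);
    w[s].resize(ms);
    totw[s] = 0.0;
    for (int i = 0; i < ms; i++) {
      rows[s][i] = rv[i] - 1;
      w[s][i] = wv[i];
      totw[s] += wv[i];
    }
    grp[s].assign(ms, 0);
    act[s].resize(ms);
    for (int i = 0; i < ms; i++) act[s][i] = i;
    relab[s].assign(2 * ms + 2, -1);
    cntW[s].assign(ms + 1, 0.0);
    cntN[s].assign(ms + 1, 0);
  }

  std::vector<int> idx;
  std::vector<double> ehhFlat;
  bool stopped = false;
  int j = core - 1 + dir;
  const int lo0 = lo - 1, hi0 = hi - 1;

  while (j >= lo0 && j <= hi0) {
    const int* col = Hp + (R_xlen_t)j * nrowH;
    double stopVal = 1.0;
    for (int s = 0; s < nset; s++) {
      std::vector<int>& A = act[s];
      if (!A.empty()) {
        std::vector<int>& G = grp[s];
        std::vector<int>& R = relab[s];
        std::vector<double>& CW = cntW[s];
        std::vector<int>& CN = cntN[s];
        std::vector<int> touched;
        touched.reserve(A.size());
        int next = 0;
        for (size_t a = 0; a < A.size(); a++) {
          int i = A[a];
          int key = 2 * G[i] + col[rows[s][i]];
          if (R[key] < 0) { R[key] = next++; touched.push_back(key); }
          G[i] = R[key];
        }
        for (size_t a = 0; a < A.size(); a++) {
          int g = G[A[a]];
          CW[g] += w[s][A[a]];
          CN[g] += 1;
        }
        double multi = 0.0;
        for (int k = 0; k < next; k++)
          if (CN[k] > 1) multi += CW[k] * (CW[k] - 1.0);
        // retire singleton-pattern classes: they can never split again
        size_t keep = 0;
        for (size_t a = 0; a < A.size(); a++) {
          int i = A[a];
          if (CN[G[i]] == 1) {
            frozen[s] += w[s][i] * (w[s][i] - 1.0);
          } else {
            A[keep++] = i;
          }
        }
        A.resize(keep);
        lastEhh[s] = (frozen[s] + multi) / (totw[s] * (totw[s] - 1.0));
        // clear scratch for the next step
        for (size_t t = 0; t < touched.size(); t++) R[touched[t]] = -1;
        for (int k = 0; k < next; k++) { CW[k] = 0.0; CN[k] = 0; }
      }
      ehhFlat.push_back(lastEhh[s]);
      if (s == stopSet - 1) stopVal = lastEhh[s];
    }
    idx.push_back(j + 1);
    if (stopVal < cutoff) { stopped = true; break; }
    if (act[stopSet - 1].empty()) break;  // plateau: can never truncate
    j += dir;
  }

  int steps = idx.size();
  NumericMatrix ehh(steps, nset);
  for (int t = 0; t < steps; t++)
    for (int s = 0; s < nset; s++)
      ehh(t, s) = ehhFlat[t * nset + s];
  return List::create(_["idx"] = wrap(idx), _["ehh"] = ehh,
                      _["stopped"] = stopped);
}
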