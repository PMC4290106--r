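#include <Rcpp.h>
using namespace Rcpp;

// Per-row G+C and A+T counts of an alignment character matrix in one
// pass (CHARSXPs are interned, so pointer comparison suffices).
// [[Rcpp::export]]
IntegerMatrix gc_at_counts_cpp(const CharacterMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  const SEXP sG = Rf_mkChar("G"), sC = Rf_mkChar("C");
  const SEXP sA = Rf_mkChar("A"), sT = Rf_mkChar("T");
  IntegerMatrix out(nr, 2);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const SEXP ch = m(i, j);
      if (ch == sG || ch == sC) ++out(i, 0);
      else if (ch == sA || ch == sT) ++out(i, 1);
    }
  }
  return out;
}

// Sample child states for one branch of a phylogeny, site by site.
//
// parent: integer states in 1..4 (A,C,G,T), one per site (all genes
//   concatenated); gene: 1-based gene index per site; cum: cumulative
//   transition probabilities with one row per (gene, parent-state) pair,
//   row = (gene-1)*4 + state, and three columns P1, P1+P2, P1+P2+P3.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector evolve_states_cpp(const IntegerVector& parent,
                                const IntegerVector& gene,
                                const NumericMatrix& cum) {
  const R_xlen_t n = parent.size();
  if (gene.size() != n) stop("parent and gene lengths differ");
  const R_xlen_t nr = cum.nrow();
  const double* c0 = cum.begin();
  const double* c1 = c0 + nr;
  const double* c2 = c1 + nr;
  const int* pp = INTEGER(parent);
  const int* pg = INTEGER(gene);
  IntegerVector child(no_init(n));
  int* pc = INTEGER(child);
  for (R_xlen_t i = 0; i < n; ++i) {
    const R_xlen_t row = (R_xlen_t)(pg[i] - 1) * 4 + (pp[i] - 1);
    if (row < 0 || row >= nr) stop("state/gene index out of range");
    const double u = unif_rand();
    int s = 1;
    if (u > c0[row]) ++s;
    if (u > c1[row]) ++s;
    if (u > c2[row]) ++s;
    pc[i] = s;
  }
  return child;
}
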