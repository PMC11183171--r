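#include <Rcpp.h>
using namespace Rcpp;

// Pairwise abundance-weighted beta mean nearest taxon distance.
// comm: samples x taxa abundances (weights are normalized internally, so
// counts or relative abundances are equivalent); D: taxa x taxa
// phylogenetic distances in the same column order as comm.
// For a pair (a, b): 0.5 * (sum_i f_ai min_j d_ij + sum_j f_bj min_i d_ij)
// over taxa present in each community, f the within-community relative
// abundances.  A taxon shared by both communities has nearest distance 0.
// [[Rcpp::export]]
NumericMatrix bmntd_pairwise_cpp(NumericMatrix comm, NumericMatrix D) {
  const int S = comm.nrow(), p = comm.ncol();
  if (D.nrow() != p || D.ncol() != p)
    stop("distance matrix does not match the community matrix");
  std::vector< std::vector<int> > pres(S);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < p; ++j)
      if (comm(s, j) > 0) pres[s].push_back(j);
  NumericMatrix out(S, S);
  for (int a = 0; a < S; ++a) {
    for (int b = a + 1; b < S; ++b) {
      if (pres[a].empty() || pres[b].empty())
        stop("empty community");
      double ta = 0.0, wa = 0.0, tb = 0.0, wb = 0.0;
      for (size_t ii = 0; ii < pres[a].size(); ++ii) {
        const int i = pres[a][ii];
        double mn = R_PosInf;
        for (size_t jj = 0; jj < pres[b].size(); ++jj) {
          const double d = D(i, pres[b][jj]);
          if (d < mn) mn = d;
        }
        ta += comm(a, i) * mn;
        wa += comm(a, i);
      }
      for (size_t jj = 0; jj < pres[b].size(); ++jj) {
        const int j = pres[b][jj];
        double mn = R_PosInf;
        for (size_t ii = 0; ii < pres[a].size(); ++ii) {
          const double d = D(pres[a][ii], j);
          if (d < mn) mn = d;
        }
        tb += comm(b, j) * mn;
        wb += comm(b, j);
      }
      const double v = 0.5 * (ta / wa + tb / wb);
      out(a, b) = v;
      out(b, a) = v;
    }
  }
  return out;
}
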