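#include <Rcpp.h>
using namespace Rcpp;

// Per-motif aggregation of neighborhood counts over a sparse presence
// matrix and a fixed neighbor graph.
//
// For every motif column j of the presence matrix P (CSC slots p_i/p_p,
// genes in rows), compute over genes g the neighborhood counts
// c_g = #{out-neighbors of g that are positive for j}, and return the
// three aggregates the scoring functions need:
//   sum_a[j] = sum_g a_lookup[c_g]   (a_lookup[0] must be 0)
//   sum_c[j] = sum_g c_g
//   max_c[j] = max_g c_g
// in_nb/in_ptr give, per gene i, the list of genes g whose out-neighbor
// list contains i (0-based CSC layout). perm relabels presence rows
// (gene i's presence is attributed to gene perm[i]); used for the
// shuffle null.
// [[Rcpp::export]]
List qmer_count_stats(IntegerVector p_i, IntegerVector p_p,
                      IntegerVector in_nb, IntegerVector in_ptr,
                      int n, NumericVector a_lookup, IntegerVector perm) {
  int ncol = p_p.size() - 1;
  NumericVector sum_a(ncol), sum_c(ncol);
  IntegerVector max_c(ncol);
  std::vector<int> counts(n, 0);
  std::vector<int> touched;
  touched.reserve(n);
  for (int j = 0; j < ncol; ++j) {
    touched.clear();
    for (int z = p_p[j]; z < p_p[j + 1]; ++z) {
      int i = perm[p_i[z]];
      for (int w = in_ptr[i]; w < in_ptr[i + 1]; ++w) {
        int g = in_nb[w];
        if (counts[g]++ == 0) touched.push_back(g);
      }
    }
    double sa = 0.0, sc = 0.0;
    int mx = 0;
    for (size_t t = 0; t < touched.size(); ++t) {
      int g = touched[t];
      int c = counts[g];
      sa += a_lookup[c];
      sc += c;
      if (c > mx) mx = c;
      counts[g] = 0;
    }
    sum_a[j] = sa;
    sum_c[j] = sc;
    max_c[j] = mx;
  }
  return List::create(_["sum_a"] = sum_a, _["sum_c"] = sum_c,
                      _["max_c"] = max_c);
}
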