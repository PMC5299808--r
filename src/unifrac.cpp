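#include <Rcpp.h>
using namespace Rcpp;

// Pairwise UniFrac distances from a branch profile, all variants in one
// pass over the branches.
//
// pt: branches x samples matrix of per-branch read fractions (transposed
//     so each sample's profile is contiguous)
// l: branch lengths
// alphas: exponents of the generalized variants to compute (may be empty)
// unweighted: also compute the presence/absence variant
//
// Returns a list of n x n distance matrices: one per alpha, then (last)
// the unweighted matrix if requested. Branches with p_A + p_B = 0 are
// omitted from the generalized sums.
// [[Rcpp::export(name = ".unifrac_pairs_multi")]]
List unifrac_pairs_multi(const NumericMatrix& pt,
                         const NumericVector& l,
                         const NumericVector& alphas,
                         bool unweighted) {
  const int e = pt.nrow(), n = pt.ncol();
  const int na = alphas.size();
  const int nv = na + (unweighted ? 1 : 0);
  if (nv == 0) stop("no variant requested");

  List out(nv);
  std::vector<double*> dptr(nv);
  for (int v = 0; v < nv; ++v) {
    NumericMatrix m(n, n);
    out[v] = m;
    dptr[v] = REAL(m);
  }
  std::vector<double> num(nv), den(nv);
  const double* lb = REAL(l);

  for (int i = 0; i < n - 1; ++i) {
    const double* pi = &pt(0, i);
    for (int j = i + 1; j < n; ++j) {
      const double* pj = &pt(0, j);
      std::fill(num.begin(), num.end(), 0.0);
      std::fill(den.begin(), den.end(), 0.0);
      for (int b = 0; b < e; ++b) {
        const double pa = pi[b], pb = pj[b], lw = lb[b];
        const double s = pa + pb;
        if (s > 0.0) {
          const double ad = std::fabs(pa - pb);
          for (int v = 0; v < na; ++v) {
            const double a = alphas[v];
            double w;
            if (a == 1.0)      w = s;
            else if (a == 0.5) w = std::sqrt(s);
            else if (a == 0.0) w = 1.0;
            else               w = std::pow(s, a);
            num[v] += lw * w * ad / s;
            den[v] += lw * w;
          }
          if (unweighted) {
            const bool ia = pa > 0.0, ib = pb > 0.0;
            if (ia != ib) num[na] += lw;
            den[na] += lw;  // s > 0 means at least one present
          }
        }
      }
      for (int v = 0; v < nv; ++v) {
        if (den[v] == 0.0)
          stop("undefined distance: samples %d and %d share no occupied "
               "branches", i + 1, j + 1);
        dptr[v][i + (R_xlen_t)n * j] = dptr[v][j + (R_xlen_t)n * i] =
          num[v] / den[v];
      }
    }
  }
  return out;
}
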