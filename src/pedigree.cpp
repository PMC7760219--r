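#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// All pedigree vectors are 0-based indices into a topologically sorted
// ordering (parents precede offspring); -1 encodes an unknown parent.

// Tabular (recursive) numerator relationship matrix.
// a_ii = 1 + 0.5 * a_{sire,dam}; a_ij = 0.5 * (a_{j,sire_i} + a_{j,dam_i}).
// [[Rcpp::export]]
arma::mat build_A_cpp(const IntegerVector& sire, const IntegerVector& dam) {
  const int n = sire.size();
  arma::mat A(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double aij = 0.0;
      if (s >= 0) aij += 0.5 * A(j, s);
      if (d >= 0) aij += 0.5 * A(j, d);
      A(i, j) = A(j, i) = aij;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

// Inbreeding coefficients by the Meuwissen & Luo recursion on A = L D L'.
// Runs in O(n * mean pedigree depth) memory-light, no dense A required.
// [[Rcpp::export]]
NumericVector inbreeding_cpp(const IntegerVector& sire, const IntegerVector& dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    const double Fs = (s >= 0) ? F[s] : -1.0;
    const double Fd = (d >= 0) ? F[d] : -1.0;
    D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s < 0 && d < 0) { F[i] = 0.0; continue; }
    // accumulate a_ii = sum_j L_ij^2 D_j by walking ancestors from i down
    double aii = 0.0;
    L[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      const double lj = L[j];
      aii += lj * lj * D[j];
      if (sire[j] >= 0) L[sire[j]] += 0.5 * lj;
      if (dam[j] >= 0)  L[dam[j]]  += 0.5 * lj;
      L[j] = 0.0;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Direct inverse of A by Henderson's rules, generalized for inbreeding:
// Mendelian-sampling variance d_i = 0.5 - 0.25 (F_s + F_d), with F = -1
// substituted for an unknown parent (giving 3/4 and 1 in the classic
// non-inbred one-/zero-parent cases).
// [[Rcpp::export]]
arma::mat ainverse_cpp(const IntegerVector& sire, const IntegerVector& dam,
                       const NumericVector& F) {
  const int n = sire.size();
  arma::mat Ai(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    const double Fs = (s >= 0) ? F[s] : -1.0;
    const double Fd = (d >= 0) ? F[d] : -1.0;
    const double b = 1.0 / (0.5 - 0.25 * (Fs + Fd));
    Ai(i, i) += b;
    if (s >= 0) { Ai(i, s) -= 0.5 * b; Ai(s, i) -= 0.5 * b; Ai(s, s) += 0.25 * b; }
    if (d >= 0) { Ai(i, d) -= 0.5 * b; Ai(d, i) -= 0.5 * b; Ai(d, d) += 0.25 * b; }
    if (s >= 0 && d >= 0) { Ai(s, d) += 0.25 * b; Ai(d, s) += 0.25 * b; }
  }
  return Ai;
}
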