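#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Minimal RMSD after optimal rigid superposition (rotation + translation,
// no reflection), via SVD of the covariance matrix.
static double kabsch(const arma::mat &A, const arma::mat &B) {
  // A, B: m x 3
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca, Bc = B.each_row() - cb;
  arma::mat C = Ac.t() * Bc; // 3 x 3
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, C);
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  double tr = s(0) + s(1) + d * s(2);
  double e = (arma::accu(Ac % Ac) + arma::accu(Bc % Bc) - 2.0 * tr) / A.n_rows;
  return e > 0 ? std::sqrt(e) : 0.0;
}

// [[Rcpp::export(name = ".cpp_kabsch_rmsd")]]
double cpp_kabsch_rmsd(NumericMatrix a, NumericMatrix b) {
  arma::mat A(a.begin(), a.nrow(), 3, false), B(b.begin(), b.nrow(), 3, false);
  return kabsch(A, B);
}

// Minimum Kabsch RMSD over the n cyclic relabelings of b's residues.
// Rows of a and b are grouped per residue (aper consecutive rows each).
// Offset o matches residue i of a with residue i + o (mod n) of b.
// [[Rcpp::export(name = ".cpp_cyclic_min_rmsd")]]
List cpp_cyclic_min_rmsd(NumericMatrix a, NumericMatrix b, int nres,
                         int aper) {
  arma::mat A(a.begin(), a.nrow(), 3, false), B(b.begin(), b.nrow(), 3, false);
  double best = R_PosInf;
  int best_o = 0;
  arma::mat Bo(B.n_rows, 3);
  for (int o = 0; o < nres; ++o) {
    for (int rr = 0; rr < nres; ++rr) {
      int src = ((rr + o) % nres) * aper;
      Bo.rows(rr * aper, rr * aper + aper - 1) =
          B.rows(src, src + aper - 1);
    }
    double v = kabsch(A, Bo);
    if (v < best) { best = v; best_o = o; }
  }
  return List::create(Named("rmsd") = best, Named("offset") = best_o);
}
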