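// Pairwise minimal RMSD between pre-centered frames via Kabsch: for
// centered coordinate sets A, B (n x 3), the optimal proper rotation is
// R = V diag(1, 1, d) U' with C = A'B = U S V' and d = sign(det(V U')).
// The RMSD is computed from the explicit residuals A R' - B rather than
// the singular-value trace identity, which loses half the significant
// digits to cancellation for near-identical frames.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat pairwise_rmsd_cpp(const arma::cube& frames) {
  const arma::uword n_beads = frames.n_rows;
  const arma::uword nf = frames.n_slices;
  arma::mat out(nf, nf, arma::fill::zeros);
  arma::mat C(3, 3), U, V, R;
  arma::vec s;
  for (arma::uword i = 0; i + 1 < nf; ++i) {
    const arma::mat& A = frames.slice(i);
    for (arma::uword j = i + 1; j < nf; ++j) {
      const arma::mat& B = frames.slice(j);
      C = A.t() * B;
      if (!arma::svd(U, s, V, C)) {
        Rcpp::stop("SVD failed for frame pair (%d, %d)", (int)i + 1,
                   (int)j + 1);
      }
      double d = (arma::det(V * U.t()) < 0.0) ? -1.0 : 1.0;
      arma::mat D = arma::eye(3, 3);
      D(2, 2) = d;
      R = V * D * U.t();
      double msd = arma::accu(arma::square(A * R.t() - B)) /
                   (double)n_beads;
      double r = std::sqrt(msd);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}
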