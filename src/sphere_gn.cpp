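// Gauss-Newton refinement of the geometric sphere-fit residuals
//   res_i = |x_i - c| - r
// from a given start, with backtracking line search (the objective valley
// is extremely shallow along the center-depth/radius direction for
// near-flat patches, where full Gauss-Newton steps overshoot). Returns
// (cx, cy, cz, r, ss, ok); ok = 0 flags a degenerate iteration (center
// collapsing onto a data point or the radius leaving (0, 1e8]); the last
// valid state and its sum of squares are still reported so the caller can
// compare candidates.
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static double sphere_ss(const arma::mat& P, const arma::vec& center,
                        double radius) {
  arma::mat U = P;
  U.each_row() -= center.t();
  arma::vec d = arma::sqrt(arma::sum(arma::square(U), 1));
  return arma::accu(arma::square(d - radius));
}

// [[Rcpp::export]]
arma::vec sphere_gn_cpp(const arma::mat& P, arma::vec center, double radius,
                        int max_iter = 200) {
  const arma::uword n = P.n_rows;
  arma::mat J(n, 4);
  arma::vec d(n), res(n), step;
  double ok = 1.0;
  double ss = sphere_ss(P, center, radius);
  for (int iter = 0; iter < max_iter; ++iter) {
    arma::mat U = P;
    U.each_row() -= center.t();
    d = arma::sqrt(arma::sum(arma::square(U), 1));
    if (d.min() < 1e-12) { ok = 0.0; break; }
    res = d - radius;
    arma::mat Un = U;
    Un.each_col() /= d;
    J.cols(0, 2) = -Un;
    J.col(3).fill(-1.0);
    arma::vec rhs = -res;
    if (!arma::solve(step, J, rhs)) { ok = 0.0; break; }
    if (!step.is_finite()) { ok = 0.0; break; }
    // backtracking: halve the step until the objective stops increasing
    double lambda = 1.0;
    arma::vec c_new;
    double r_new = radius, ss_new = ss;
    bool accepted = false;
    for (int bt = 0; bt < 40; ++bt) {
      c_new = center + lambda * step.subvec(0, 2);
      r_new = radius + lambda * step(3);
      if (std::isfinite(r_new) && r_new > 0.0 && r_new <= 1e8) {
        ss_new = sphere_ss(P, c_new, r_new);
        if (ss_new <= ss * (1.0 + 1e-15)) { accepted = true; break; }
      }
      lambda *= 0.5;
    }
    if (!accepted) break;
    center = c_new;
    radius = r_new;
    ss = ss_new;
    if (lambda * arma::abs(step).max() < 1e-13 * std::max(radius, 1.0)) {
      break;
    }
  }
  arma::vec out(6);
  out(0) = center(0); out(1) = center(1); out(2) = center(2);
  out(3) = radius; out(4) = ss; out(5) = ok;
  return out;
}
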