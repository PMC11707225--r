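#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-sample least-squares rigid-body fit (orthogonal Procrustes with a
// proper-rotation constraint) of an observed marker cluster to its
// template local coordinates.
//
// obs:   T x 3M matrix, columns X1,Y1,Z1,X2,... (metres, lab frame)
// local: M x 3 template coordinates (metres, segment frame)
//
// Returns rot (T x 9, column-major 3x3 per row) and origin (T x 3) such
// that obs_i ~= R * local_i + origin in the least-squares sense.
// [[Rcpp::export]]
List rigid_fit_cpp(const arma::mat& obs, const arma::mat& local) {
  const arma::uword n = obs.n_rows;
  const arma::uword m = local.n_rows;
  if (obs.n_cols != 3 * m) stop("obs must have 3 columns per template marker");

  arma::rowvec lbar = arma::mean(local, 0);
  arma::mat lc = local.each_row() - lbar;   // M x 3 centred template

  arma::mat rot(n, 9);
  arma::mat origin(n, 3);
  arma::mat B(m, 3), H(3, 3), U, V, R;
  arma::vec s;

  for (arma::uword t = 0; t < n; ++t) {
    for (arma::uword i = 0; i < m; ++i) {
      B(i, 0) = obs(t, 3 * i);
      B(i, 1) = obs(t, 3 * i + 1);
      B(i, 2) = obs(t, 3 * i + 2);
    }
    arma::rowvec bbar = arma::mean(B, 0);
    B.each_row() -= bbar;
    H = lc.t() * B;                         // 3x3 cross-covariance
    if (!arma::svd(U, s, V, H)) stop("SVD failure in rigid fit");
    R = V * U.t();
    if (arma::det(R) < 0) {                 // enforce proper rotation
      V.col(2) *= -1.0;
      R = V * U.t();
    }
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        rot(t, 3 * c + r) = R(r, c);
    arma::vec o = bbar.t() - R * lbar.t();
    origin(t, 0) = o(0);
    origin(t, 1) = o(1);
    origin(t, 2) = o(2);
  }
  return List::create(_["rot"] = rot, _["origin"] = origin);
}
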