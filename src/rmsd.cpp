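// Kabsch least-squares superposition RMSD.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// frames: F x (3n) matrix, row = concatenated coordinates (x1 y1 z1 x2 ...).
static double kabsch_rmsd(const arma::rowvec &a, const arma::rowvec &b) {
  const int n = a.n_elem / 3;
  arma::mat A(reinterpret_cast<const double *>(a.memptr()), 3, n);
  arma::mat B(reinterpret_cast<const double *>(b.memptr()), 3, n);
  arma::vec ca = arma::mean(A, 1), cb = arma::mean(B, 1);
  A.each_col() -= ca;
  B.each_col() -= cb;
  arma::mat H = B * A.t(); // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failure in RMSD");
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  double e = arma::accu(arma::square(A)) + arma::accu(arma::square(B));
  double tr = s(0) + s(1) + d * s(2);
  double msd = std::max(0.0, (e - 2.0 * tr) / n);
  return std::sqrt(msd);
}

// [[Rcpp::export]]
double cpp_rmsd_pair(NumericVector a, NumericVector b) {
  arma::rowvec ra(a.begin(), a.size());
  arma::rowvec rb(b.begin(), b.size());
  return kabsch_rmsd(ra, rb);
}

// [[Rcpp::export]]
NumericMatrix cpp_rmsd_matrix(NumericMatrix frames) {
  const int F = frames.nrow();
  arma::mat X(frames.begin(), F, frames.ncol(), false);
  NumericMatrix out(F, F);
  for (int i = 0; i < F; ++i) {
    arma::rowvec ri = X.row(i);
    for (int j = i + 1; j < F; ++j) {
      double r = kabsch_rmsd(ri, X.row(j));
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}

// RMSD of every frame against a set of reference frames.
// [[Rcpp::export]]
NumericMatrix cpp_rmsd_to_refs(NumericMatrix frames, NumericMatrix refs) {
  const int F = frames.nrow(), R = refs.nrow();
  arma::mat X(frames.begin(), F, frames.ncol(), false);
  arma::mat Y(refs.begin(), R, refs.ncol(), false);
  NumericMatrix out(F, R);
  for (int i = 0; i < F; ++i)
    for (int j = 0; j < R; ++j) out(i, j) = kabsch_rmsd(X.row(i), Y.row(j));
  return out;
}
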