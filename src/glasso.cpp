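// Block coordinate descent for l1-penalized precision estimation.
// Each column update solves min_b 0.5 b'Vb - s'b + lam|b|_1 by coordinate
// descent; the precision is rebuilt from the block-inverse identities after
// every sweep and iteration stops when the sum of absolute entrywise
// changes falls below `tol`.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static void lasso_cd(const mat& V, const vec& s, double lam, vec& beta,
                     double tol, int max_iter) {
  const int K = s.n_elem;
  vec r = s - V * beta;                      // negative gradient
  for (int it = 0; it < max_iter; ++it) {
    double max_change = 0.0;
    for (int k = 0; k < K; ++k) {
      const double bk_old = beta[k];
      const double z = r[k] + V(k, k) * bk_old;
      double bk = 0.0;
      const double az = std::abs(z) - lam;
      if (az > 0.0) bk = (z > 0.0 ? az : -az) / V(k, k);
      if (bk != bk_old) {
        beta[k] = bk;
        r -= V.col(k) * (bk - bk_old);
        const double ch = std::abs(bk - bk_old);
        if (ch > max_change) max_change = ch;
      }
    }
    if (max_change < tol) break;
  }
}

// [[Rcpp::export(name = ".glasso_bcd")]]
Rcpp::List glasso_bcd(const arma::mat& S, double lam, double diag_add,
                      double tol, int max_iter, double inner_tol,
                      int inner_max_iter) {
  const int R = S.n_rows;
  mat W = S;
  W.diag() += diag_add;
  mat B(R - 1, R, fill::zeros);
  mat theta(R, R, fill::zeros);
  mat theta_prev = diagmat(1.0 / W.diag());
  std::vector<double> trace;
  bool converged = false;

  std::vector<uvec> not_j(R);
  for (int j = 0; j < R; ++j) {
    uvec idx(R - 1);
    int c = 0;
    for (int k = 0; k < R; ++k) if (k != j) idx[c++] = k;
    not_j[j] = idx;
  }

  for (int it = 0; it < max_iter; ++it) {
    for (int j = 0; j < R; ++j) {
      const uvec& idx = not_j[j];
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      vec s12e = s12.elem(idx);
      vec beta = B.col(j);
      lasso_cd(W11, s12e, lam, beta, inner_tol, inner_max_iter);
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (int k = 0; k < R - 1; ++k) {
        W(idx[k], j) = w12[k];
        W(j, idx[k]) = w12[k];
      }
    }
    // precision from the working covariance and the column coefficients
    for (int j = 0; j < R; ++j) {
      const uvec& idx = not_j[j];
      vec beta = B.col(j);
      vec wj = W.col(j);
      double denom = W(j, j) - dot(wj.elem(idx), beta);
      const double tjj = 1.0 / denom;
      theta(j, j) = tjj;
      for (int k = 0; k < R - 1; ++k) theta(idx[k], j) = -beta[k] * tjj;
    }
    theta = (theta + theta.t()) / 2.0;
    const double dtheta = accu(abs(theta - theta_prev));
    trace.push_back(dtheta);
    theta_prev = theta;
    if (dtheta < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("theta") = theta,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged);
}
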