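// Cross-validated shrinkage-LDA decision values, per timebin.
//
// The discriminant is w = Sigma_reg^-1 (mu1 - mu0) with
// Sigma_reg = (1 - lambda) S + lambda nu I, where S is the pooled
// within-class covariance (MLE), nu = tr(S)/p, and lambda the analytic
// Ledoit-Wolf shrinkage intensity. The bias places the boundary midway
// between the projected class means; class 1 projects positive.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Pooled within-class centered data -> shrinkage intensity + regularized cov.
static void lw_fit(const mat& X, const uvec& i0, const uvec& i1,
                   vec& w, double& b, double& lambda) {
  const uword p = X.n_cols;
  const double n = (double)(i0.n_elem + i1.n_elem);
  rowvec mu0 = mean(X.rows(i0), 0);
  rowvec mu1 = mean(X.rows(i1), 0);
  mat Z(i0.n_elem + i1.n_elem, p);
  Z.rows(0, i0.n_elem - 1) = X.rows(i0) - repmat(mu0, i0.n_elem, 1);
  Z.rows(i0.n_elem, Z.n_rows - 1) = X.rows(i1) - repmat(mu1, i1.n_elem, 1);
  mat S = (Z.t() * Z) / n;
  double nu = trace(S) / (double)p;
  // analytic shrinkage toward nu * I (Ledoit-Wolf)
  vec zsq = sum(square(Z), 1);
  double frob_S = accu(square(S));
  double phi = accu(square(zsq)) / n - frob_S;  // (1/n) sum ||zz' - S||^2_F
  mat D = S; D.diag() -= nu;
  double delta = accu(square(D));
  lambda = 0.0;
  if (delta > 0) lambda = (phi / n) / delta;
  if (lambda < 0) lambda = 0;
  if (lambda > 1) lambda = 1;
  mat Sreg = (1.0 - lambda) * S;
  Sreg.diag() += lambda * nu + 1e-12 * (nu > 0 ? nu : 1.0);
  vec d = (mu1 - mu0).t();
  w = solve(Sreg, d, solve_opts::likely_sympd);
  b = -dot(w, 0.5 * (mu0 + mu1).t());
}

// [[Rcpp::export]]
Rcpp::List cpp_lda_fit(const arma::mat& X, const arma::ivec& y) {
  uvec i0 = find(y == 0), i1 = find(y == 1);
  if (i0.n_elem < 2 || i1.n_elem < 2)
    Rcpp::stop("each class needs >= 2 trials");
  vec w; double b, lambda;
  lw_fit(X, i0, i1, w, b, lambda);
  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("lambda") = lambda);
}

// X: trials x scales x timebins; y in {0,1}; folds: trials x repeats with
// fold ids (1..k). Returns trials x timebins out-of-fold decision values,
// averaged over repeats.
// [[Rcpp::export]]
arma::mat cpp_cv_dvalues(const arma::cube& X, const arma::ivec& y,
                         const arma::imat& folds) {
  const uword n = X.n_rows, nb = X.n_slices, nrep = folds.n_cols;
  if (y.n_elem != n || folds.n_rows != n)
    Rcpp::stop("label/fold dimensions do not match the feature array");
  mat D(n, nb, fill::zeros);
  for (uword b = 0; b < nb; ++b) {
    const mat& F = X.slice(b);
    for (uword r = 0; r < nrep; ++r) {
      int kmax = folds.col(r).max();
      for (int k = 1; k <= kmax; ++k) {
        uvec test = find(folds.col(r) == k);
        if (test.n_elem == 0) continue;
        uvec train = find(folds.col(r) != k);
        ivec ytr = y.elem(train);
        uvec i0 = find(ytr == 0), i1 = find(ytr == 1);
        if (i0.n_elem < 2 || i1.n_elem < 2)
          Rcpp::stop("a training fold has a class with < 2 trials");
        vec w; double bias, lambda;
        lw_fit(F.rows(train), i0, i1, w, bias, lambda);
        for (uword t = 0; t < test.n_elem; ++t)
          D(test(t), b) += dot(F.row(test(t)), w) + bias;
      }
    }
  }
  return D / (double)nrep;
}
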