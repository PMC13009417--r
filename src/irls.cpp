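// Newton solvers for the pooled logistic weight models and the weighted
// least-squares outcome model. These run once per bootstrap replicate on
// frozen design matrices, so they are the innermost loop of the package.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted logistic Newton iteration; ok = false signals the caller to fall
// back to the reference fitter (stats::glm.fit).
// [[Rcpp::export]]
Rcpp::List cpp_logit_irls(const arma::mat& X, const arma::vec& y, const arma::vec& w,
                          const arma::vec& start, double tol, int maxit) {
  vec beta = start;
  const uword k = X.n_cols;
  bool ok = false;
  for (int it = 0; it < maxit; ++it) {
    vec p = 1.0 / (1.0 + exp(-(X * beta)));
    vec wm = w % clamp(p % (1.0 - p), 1e-10, datum::inf);
    mat H(k, k);
    vec g(k);
    H = X.t() * (X.each_col() % wm);
    g = X.t() * (w % (y - p));
    vec step;
    bool solved = solve(step, H, g,
                        solve_opts::likely_sympd + solve_opts::no_approx);
    if (!solved) return Rcpp::List::create(Rcpp::Named("ok") = false);
    beta += step;
    if (abs(step).max() < tol) { ok = true; break; }
  }
  return Rcpp::List::create(Rcpp::Named("ok") = ok,
                            Rcpp::Named("beta") = beta);
}

// Weighted least squares via the normal equations.
// [[Rcpp::export]]
Rcpp::List cpp_wls(const arma::mat& X, const arma::vec& y, const arma::vec& w) {
  mat H = X.t() * (X.each_col() % w);
  vec b;
  bool solved = solve(b, H, X.t() * (w % y),
                      solve_opts::likely_sympd + solve_opts::no_approx);
  return Rcpp::List::create(Rcpp::Named("ok") = solved,
                            Rcpp::Named("beta") = b);
}
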