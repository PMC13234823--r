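// Fast logistic-regression Wald p-values for the feature coefficient,
// used by the permutation-based class enrichment analysis where each of
// B phenotype permutations refits one logistic model per feature.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// IRLS for logit(P(y=1)) = b0 + b1 * x + C * g. Returns the two-sided
// Wald p-value of b1; 1.0 on non-convergence / degeneracy. A small ridge
// is applied on (quasi-)separation so the Wald statistic stays finite.
static double wald_p_one(const vec &x, const vec &y, const mat &C) {
  const uword n = x.n_elem;
  const uword p = 2 + C.n_cols;
  mat X(n, p);
  X.col(0).ones();
  X.col(1) = x;
  if (C.n_cols > 0) X.cols(2, p - 1) = C;

  if (stddev(x) < 1e-12) return 1.0; // constant feature

  vec beta(p, fill::zeros);
  double ridge = 0.0;
  bool converged = false;
  for (int iter = 0; iter < 50; ++iter) {
    vec eta = X * beta;
    eta = clamp(eta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w = clamp(w, 1e-10, 0.25);
    mat XtWX = X.t() * (X.each_col() % w);
    XtWX.diag() += ridge;
    vec z = eta + (y - mu) / w;
    vec beta_new;
    bool ok = solve(beta_new, XtWX, X.t() * (w % z), solve_opts::no_approx);
    if (!ok) { ridge = std::max(ridge * 10.0, 1e-4); continue; }
    double step = norm(beta_new - beta, "inf");
    beta = beta_new;
    if (step < 1e-8) { converged = true; break; }
    // separation guard: exploding coefficients -> penalized refit
    if (norm(beta, "inf") > 50.0 && ridge == 0.0) {
      ridge = 1e-3 * n;
      beta.zeros();
    }
  }
  if (!converged) return 1.0;
  vec eta = clamp(X * beta, -30.0, 30.0);
  vec mu = 1.0 / (1.0 + exp(-eta));
  vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
  mat XtWX = X.t() * (X.each_col() % w);
  XtWX.diag() += ridge;
  mat cov;
  if (!inv_sympd(cov, XtWX)) return 1.0;
  double se = std::sqrt(cov(1, 1));
  if (!std::isfinite(se) || se <= 0) return 1.0;
  double zstat = beta(1) / se;
  return 2.0 * R::pnorm(-std::fabs(zstat), 0.0, 1.0, 1, 0);
}

// p-values for every feature (columns of xmat) under the observed labels
// and under each permutation (columns of perms hold permuted 0/1 labels).
// Returns an F x (1 + B) matrix: column 1 observed, then permutations.
// [[Rcpp::export]]
arma::mat cpp_logistic_pvals(const arma::mat &xmat, const arma::vec &y,
                             const arma::mat &covs, const arma::mat &perms) {
  const uword F = xmat.n_cols;
  const uword B = perms.n_cols;
  mat out(F, 1 + B);
  for (uword f = 0; f < F; ++f) {
    out(f, 0) = wald_p_one(xmat.col(f), y, covs);
    for (uword b = 0; b < B; ++b)
      out(f, 1 + b) = wald_p_one(xmat.col(f), perms.col(b), covs);
    if (f % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
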