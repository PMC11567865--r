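// Graphical lasso by block coordinate descent (Friedman-Hastie-Tibshirani).
// Estimates a sparse precision matrix Theta maximizing
//   log det Theta - tr(R Theta) - lambda * sum_{i != j} |Theta_ij|
// (penalty on off-diagonal entries only, so diag(W) = diag(R)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso sub-problem by coordinate descent:
//   min_beta 1/2 beta' V beta - s' beta + lambda |beta|_1
static void lasso_cd(const mat& V, const vec& s, double lambda, vec& beta,
                     int maxit, double tol) {
  const uword q = s.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < q; ++j) {
      double old = beta(j);
      // residual gradient excluding j
      double r = s(j) - dot(V.col(j), beta) + V(j, j) * old;
      double bj = soft(r, lambda) / V(j, j);
      beta(j) = bj;
      double d = std::abs(bj - old);
      if (d > dmax) dmax = d;
    }
    if (dmax < tol) break;
  }
}

static std::vector<uvec> column_index_sets(uword p) {
  std::vector<uvec> sets(p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword k = 0;
    for (uword i = 0; i < p; ++i) if (i != j) idx(k++) = i;
    sets[j] = idx;
  }
  return sets;
}

// One glasso fit. W and B (p x p, column j = beta for column j) are
// modified in place so a path can warm-start.
static int glasso_core(const mat& R, double lambda, mat& W, mat& B,
                       int maxit_outer, int maxit_inner, double tol,
                       const std::vector<uvec>& idxs) {
  const uword p = R.n_rows;
  const double mean_off = p > 1 ? accu(abs(R - diagmat(R.diag()))) / (p * (p - 1)) : 0.0;
  const double thr = tol * std::max(mean_off, 1e-12);
  mat V(p - 1, p - 1);
  vec s(p - 1), beta(p - 1), w12(p - 1);
  int iter = 0;
  for (iter = 1; iter <= maxit_outer; ++iter) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      const uvec& idx = idxs[j];
      V = W(idx, idx);
      for (uword k = 0; k < p - 1; ++k) {
        s(k) = R(idx(k), j);
        beta(k) = B(idx(k), j);
      }
      lasso_cd(V, s, lambda, beta, maxit_inner, tol * 0.1);
      w12 = V * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (dmax < thr) break;
  }
  return iter;
}

// Recover Theta from converged W and B.
static mat theta_from_wb(const mat& W, const mat& B,
                         const std::vector<uvec>& idxs) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const uvec& idx = idxs[j];
    double dotwb = 0.0;
    for (uword k = 0; k < p - 1; ++k)
      dotwb += W(idx(k), j) * B(idx(k), j);
    double theta22 = 1.0 / (W(j, j) - dotwb);
    Theta(j, j) = theta22;
    for (uword k = 0; k < p - 1; ++k)
      Theta(idx(k), j) = -B(idx(k), j) * theta22;
  }
  // exact symmetrization (column solutions agree only to tolerance)
  Theta = 0.5 * (Theta + Theta.t());
  return Theta;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& R, double lambda,
                      int maxit_outer = 200, int maxit_inner = 400,
                      double tol = 1e-6) {
  const uword p = R.n_rows;
  if (lambda <= 1e-14) {
    // unpenalized MLE: plain inverse
    mat Theta = inv_sympd(symmatu(R));
    return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                              Rcpp::Named("W") = symmatu(R),
                              Rcpp::Named("iters") = 0,
                              Rcpp::Named("converged") = true);
  }
  mat W = symmatu(R);
  mat B(p, p, fill::zeros);
  std::vector<uvec> idxs = column_index_sets(p);
  int it = glasso_core(R, lambda, W, B, maxit_outer, maxit_inner, tol, idxs);
  mat Theta = theta_from_wb(W, B, idxs);
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("iters") = it,
                            Rcpp::Named("converged") = it <= maxit_outer);
}

// Path of fits with warm starts, lambdas in decreasing-penalty order or any
// order; fits proceed from largest lambda to smallest internally.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& R, const arma::vec& lambdas,
                           int maxit_outer = 200, int maxit_inner = 400,
                           double tol = 1e-6) {
  const uword p = R.n_rows;
  const uword K = lambdas.n_elem;
  uvec ord = sort_index(lambdas, "descend");
  cube thetas(p, p, K);
  ivec iters(K);
  mat W = symmatu(R);
  mat B(p, p, fill::zeros);
  std::vector<uvec> idxs = column_index_sets(p);
  for (uword k = 0; k < K; ++k) {
    uword i = ord(k);
    double lam = lambdas(i);
    if (lam <= 1e-14) {
      thetas.slice(i) = inv_sympd(symmatu(R));
      iters(i) = 0;
      continue;
    }
    int it = glasso_core(R, lam, W, B, maxit_outer, maxit_inner, tol, idxs);
    thetas.slice(i) = theta_from_wb(W, B, idxs);
    iters(i) = it;
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("iters") = iters);
}
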