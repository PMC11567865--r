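# Sparse Gaussian graphical model estimation: graphical lasso over a
# lambda path with EBIC (gamma = 0.5) model selection, conversion of the
# precision matrix to signed partial correlations, multilayer assembly.

#' Graphical lasso at a single penalty
#'
#' Maximizes `log det(Theta) - tr(R Theta) - lambda * sum_(i!=j) |Theta_ij|`
#' (L1 penalty on off-diagonals only) by block coordinate descent. At
#' `lambda = 0` the solution is the plain inverse of `R`.
#'
#' @param R p x p correlation matrix (symmetric, PSD, unit diagonal).
#' @param lambda penalty, >= 0.
#' @param tol convergence tolerance on the working covariance (default 1e-6).
#' @param maxit maximum outer sweeps.
#' @return symmetric positive-definite precision matrix `Theta`.
#' @export
glasso <- function(R, lambda, tol = 1e-6, maxit = 200) {
  R <- as.matrix(R)
  if (lambda < 0) stop("lambda must be >= 0")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda <= 1e-14 && ev <= 1e-10)
    stop("R is singular/non-PSD; repair it (see pairwise_complete_correlation) ",
         "or use lambda > 0")
  if (ev < -1e-8)
    stop("R is not PSD; repair it first (see pairwise_complete_correlation)")
  fit <- .glasso_cpp(R, lambda, maxit_outer = maxit, tol = tol)
  if (!fit$converged)
    stop(sprintf("glasso did not converge at lambda = %g", lambda))
  Theta <- fit$Theta
  Theta[abs(Theta) < 1e-12] <- 0
  dimnames(Theta) <- dimnames(R)
  Theta
}

#' Extended Bayesian information criterion for a GGM
#'
#' `EBIC = -2 L + |E| log(n) + 4 gamma |E| log(p)` with Gaussian
#' log-likelihood `L = (n/2)(log det Theta - tr(R Theta))` and `|E|` the
#' number of nonzero upper-triangle off-diagonal entries of `Theta`.
#'
#' @param Theta precision matrix (SPD).
#' @param R sample correlation matrix.
#' @param n effective sample size.
#' @param gamma EBIC hyperparameter (>= 0); 0 recovers ordinary BIC.
#' @return EBIC value (numeric scalar).
#' @export
ebic <- function(Theta, R, n, gamma = 0.5) {
  stopifnot(n > 0, gamma >= 0)
  p <- nrow(Theta)
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    stop("Theta is not positive definite")
  L <- (n / 2) * (as.numeric(ld$modulus) - sum(R * Theta))
  E <- sum(abs(Theta[upper.tri(Theta)]) > 0)
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' Fit the glasso path and select a model by EBIC
#'
#' The penalty grid is log-spaced over
#' `[lambda_min_ratio * lambda_max, lambda_max]` with
#' `lambda_max = max_(i!=j) |R_ij|` (the smallest penalty giving an empty
#' graph). The model minimizing EBIC at the given `gamma` is selected.
#'
#' @param R correlation matrix (from [pairwise_complete_correlation()]).
#' @param n effective sample size (minimum pairwise-complete count).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda grid size (default 100).
#' @param lambda_min_ratio smallest penalty relative to `lambda_max`.
#' @return object of class `ggm_fit`: `lambda_grid`, `precisions` (list of
#'   Theta along the path), `ebic_values`, `selected_index`, `gamma`,
#'   `sample_correlation`, `n_effective`.
#' @export
select_model <- function(R, n, gamma = 0.5, n_lambda = 100,
                         lambda_min_ratio = 0.01) {
  R <- as.matrix(R)
  lam_max <- max(abs(R[upper.tri(R)]))
  if (lam_max <= 0) lam_max <- 1e-4
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  path <- .glasso_path_cpp(R, lambdas)
  precisions <- lapply(seq_len(n_lambda), function(k) {
    Th <- path$thetas[, , k]
    Th[abs(Th) < 1e-12] <- 0
    dimnames(Th) <- dimnames(R)
    Th
  })
  ebics <- vapply(precisions, ebic, numeric(1), R = R, n = n, gamma = gamma)
  if (any(!is.finite(ebics))) stop("non-finite EBIC along the path")
  structure(list(lambda_grid = lambdas, precisions = precisions,
                 ebic_values = ebics, selected_index = which.min(ebics),
                 gamma = gamma, sample_correlation = R,
                 n_effective = as.integer(n)),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  k <- x$selected_index
  Th <- x$precisions[[k]]
  cat(sprintf(
    "ggm_fit: p = %d, n = %d, gamma = %g; selected lambda = %.4g (%d/%d), |E| = %d\n",
    nrow(Th), x$n_effective, x$gamma, x$lambda_grid[k], k,
    length(x$lambda_grid), sum(abs(Th[upper.tri(Th)]) > 0)))
  invisible(x)
}

#' Selected precision matrix of a fit
#' @param fit a `ggm_fit`.
#' @return the EBIC-selected precision matrix.
#' @export
selected_precision <- function(fit) fit$precisions[[fit$selected_index]]

#' Precision matrix to signed partial correlations
#'
#' `W_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)` off the diagonal,
#' `W_ii = 0`.
#'
#' @param Theta SPD precision matrix.
#' @return signed partial-correlation matrix with zero diagonal.
#' @export
to_partial_correlations <- function(Theta) {
  d <- diag(Theta)
  if (any(d <= 0)) stop("Theta has a non-positive diagonal entry")
  W <- -Theta / sqrt(tcrossprod(d))
  diag(W) <- 0
  W[abs(W) < 1e-12] <- 0
  (W + t(W)) / 2
}

#' Estimate the multilayer partial-correlation network
#'
#' Full estimation chain on Gaussianized data: pairwise-complete
#' correlation, glasso path with EBIC selection, conversion to partial
#' correlations, assembly into a [multilayer_network()] with seeded
#' Fruchterman-Reingold layout coordinates stored on the nodes.
#'
#' @param X_npn n x p matrix (already nonparanormal-transformed), columns
#'   named by node id.
#' @param node_meta node metadata data frame (see [read_node_meta()]);
#'   rows matched to columns of `X_npn` by `node_id`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio passed to [select_model()].
#' @param layout_seed seed for the layout (default 42).
#' @return list with `network` (multilayer_network) and `fit` (ggm_fit).
#' @export
estimate_multilayer <- function(X_npn, node_meta, gamma = 0.5,
                                n_lambda = 100, lambda_min_ratio = 0.01,
                                layout_seed = 42) {
  if (!all(colnames(X_npn) %in% node_meta$node_id))
    stop("columns of X_npn not covered by node_meta")
  node_meta <- node_meta[match(colnames(X_npn), node_meta$node_id), ,
                         drop = FALSE]
  pc <- pairwise_complete_correlation(X_npn)
  fit <- select_model(pc$R, pc$n_effective, gamma = gamma,
                      n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio)
  W <- to_partial_correlations(selected_precision(fit))
  net <- multilayer_network(signed_network(W, node_meta, pc$n_effective))
  xy <- with_seed(layout_seed,
                  igraph::layout_with_fr(as_igraph(net, absolute = TRUE)))
  net$nodes$x <- xy[, 1]
  net$nodes$y <- xy[, 2]
  list(network = net, fit = fit)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
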