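corr_input <- function(S) {
  if (inherits(S, "mixed_corr")) S$R else as.matrix(S)
}

#' Graphical lasso at a fixed penalty
#'
#' L1-penalised Gaussian maximum likelihood for the precision matrix:
#' maximises `log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|`
#' (diagonal unpenalised) by block coordinate descent.
#'
#' @param S correlation/covariance matrix (or a `mixed_corr`).
#' @param lambda penalty, >= 0.
#' @param tol convergence tolerance on the working covariance sweep.
#' @param maxit maximum outer sweeps.
#' @return list with `Theta` (precision), `W` (estimated covariance),
#'   `niter`, `converged`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-7, maxit = 1000) {
  S <- corr_input(S)
  if (lambda < 0) stop_arg("`lambda` must be >= 0")
  fit <- .glasso_cpp(S, lambda, tol, maxit)
  if (!fit$converged) {
    res <- kkt_residual(S, fit$Theta, fit$W, lambda)
    stop(sprintf("graphical lasso did not converge in %d sweeps (KKT residual %.3g)",
                 maxit, res))
  }
  dimnames(fit$Theta) <- dimnames(fit$W) <- dimnames(S)
  fit
}

#' Karush-Kuhn-Tucker residual of a glasso solution
#'
#' Largest violation of the stationarity conditions: for zero off-diagonal
#' precision entries `|S - W| <= lambda`, for nonzero entries
#' `S - W = -lambda * sign(Theta)`, and `diag(W) = diag(S)`.
#'
#' @param S input matrix; `Theta` precision; `W` its inverse estimate;
#'   `lambda` penalty.
#' @return maximum absolute violation.
#' @export
kkt_residual <- function(S, Theta, W, lambda) {
  S <- corr_input(S)
  G <- S - W
  off <- row(S) != col(S)
  zero <- off & (Theta == 0)
  act <- off & (Theta != 0)
  r1 <- if (any(zero)) max(pmax(abs(G[zero]) - lambda, 0)) else 0
  r2 <- if (any(act)) max(abs(G[act] + lambda * sign(Theta[act]))) else 0
  r3 <- max(abs(diag(S) - diag(W)))
  max(r1, r2, r3)
}

#' Extended Bayesian information criterion for a GGM fit
#'
#' `EBIC = -n * (log det Theta - tr(S Theta)) + E log(n) + 4 E gamma log(p)`
#' with `E` the number of nonzero upper-triangle precision entries. At
#' `gamma = 0` this is the ordinary BIC; `gamma = 0.5` is the conventional
#' choice favouring sparser, more interpretable networks.
#'
#' @param Theta precision matrix (must be SPD).
#' @param S the correlation matrix the model was fit to.
#' @param n sample size.
#' @param gamma extended-penalty hyperparameter, >= 0.
#' @return the EBIC score (smaller is better).
#' @export
ebic <- function(Theta, S, n, gamma = 0.5) {
  S <- corr_input(S)
  ch <- tryCatch(chol(Theta), error = function(e) NULL)
  if (is.null(ch)) stop_arg("`Theta` must be positive definite")
  ld <- 2 * sum(log(diag(ch)))
  fit <- ld - sum(S * Theta)
  E <- sum(Theta[upper.tri(Theta)] != 0)
  p <- ncol(Theta)
  -n * fit + E * log(n) + 4 * E * gamma * log(p)
}

pcor_from_precision <- function(Theta) {
  d <- sqrt(diag(Theta))
  W <- -Theta / tcrossprod(d)
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Sparse partial-correlation network by EBIC-selected graphical lasso
#'
#' Fits the graphical lasso along a log-spaced penalty path from
#' `lambda_max` (the largest absolute off-diagonal of `S`, above which the
#' estimate is empty) down to `lambda_max * lambda_min_ratio`, scores each
#' fit by [ebic()], and returns the partial-correlation network of the
#' minimising fit, `w_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)`.
#'
#' @param S correlation matrix or `mixed_corr`.
#' @param n number of subjects behind `S`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda path length (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @param tol,maxit passed to the glasso core.
#' @return a `ggm_network`: `nodes`, `weights` (partial correlations, zero
#'   diagonal), `lambda_selected`, `gamma`, `n`, `edge_count`, `ebic_path`
#'   (data frame over the path), `precision`.
#' @export
ebicglasso <- function(S, n, gamma = 0.5, n_lambda = 100,
                       lambda_min_ratio = 0.01, tol = 1e-7, maxit = 1000) {
  Sm <- corr_input(S)
  p <- ncol(Sm)
  if (n <= p) warning("n <= p: EBIC selection may be unreliable")
  lmax <- max(abs(Sm[upper.tri(Sm)]))
  if (lmax < 1e-12) {
    lambdas <- 0
  } else {
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = n_lambda))
  }
  path <- .glasso_path_cpp(Sm, lambdas, tol, maxit)
  if (!all(path$converged)) {
    bad <- which(!path$converged)
    stop(sprintf("glasso failed to converge at %d path point(s), e.g. lambda = %.4g",
                 length(bad), lambdas[bad[1]]))
  }
  ebics <- -n * path$fit + path$edges * log(n) +
    4 * path$edges * gamma * log(p)
  best <- which.min(ebics)  # ties resolve to the sparsest (largest lambda)
  nodes <- colnames(Sm) %||% sprintf("V%02d", seq_len(p))
  Theta <- path$Thetas[, , best]
  dimnames(Theta) <- list(nodes, nodes)
  W <- pcor_from_precision(Theta)
  dimnames(W) <- list(nodes, nodes)
  structure(list(
    nodes = nodes,
    weights = W,
    precision = Theta,
    lambda_selected = lambdas[best],
    gamma = gamma, n = n,
    edge_count = as.integer(path$edges[best]),
    ebic_path = data.frame(lambda = lambdas,
                           edges = as.integer(path$edges),
                           fit = path$fit, ebic = ebics)
  ), class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  p <- length(x$nodes)
  cat(sprintf(
    "<ggm_network> %d nodes, %d/%d edges, lambda = %.4g (gamma = %.2g, n = %d)\n",
    p, x$edge_count, p * (p - 1) / 2, x$lambda_selected, x$gamma, x$n))
  invisible(x)
}

#' Global strength of a network
#'
#' Absolute sum of edge weights over the upper triangle.
#'
#' @param net a `ggm_network` or a symmetric weight matrix.
#' @return scalar.
#' @export
global_strength <- function(net) {
  W <- if (inherits(net, "ggm_network")) net$weights else as.matrix(net)
  sum(abs(W[upper.tri(W)]))
}
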