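// Graphical lasso: L1-penalised Gaussian precision estimation by block
// coordinate descent (row/column sweeps with an inner lasso solved by
// coordinate descent). Off-diagonal entries are penalised, the diagonal is
// not, so the working covariance keeps W_ii = S_ii throughout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One full glasso fit. B holds the per-column lasso coefficients and is used
// both for warm starts along a penalty path and to back out Theta at the end.
static void glasso_core(const mat& S, double lambda, mat& W, mat& B,
                        double tol, int maxit, int& niter, bool& converged) {
  const uword p = S.n_rows;
  const double thr = tol * mean(mean(abs(S - diagmat(S.diag())))) + 1e-14;

  W.diag() = S.diag();  // diagonal unpenalised
  converged = false;
  niter = 0;
  if (p == 1) { converged = true; return; }

  vec beta(p), w12(p);
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      // solve the lasso subproblem for column j against W[-j,-j];
      // beta(j) is pinned at 0 so full-length dot products skip nothing
      beta = B.col(j);
      beta(j) = 0.0;

      // inner lasso: min 0.5 b' W11 b - s' b + lambda ||b||_1
      for (int inner = 0; inner < 1000; ++inner) {
        double dlt = 0.0;
        for (uword m = 0; m < p; ++m) {
          if (m == j) continue;
          double old = beta(m);
          double grad = S(m, j) - dot(W.col(m), beta) + W(m, m) * old;
          double bnew = soft(grad, lambda) / W(m, m);
          if (bnew != old) {
            beta(m) = bnew;
            dlt = std::max(dlt, std::fabs(bnew - old));
          }
        }
        if (dlt < thr * 0.1) break;
      }

      w12 = W * beta;  // beta(j) = 0, so row/col j of W drop out
      double dj = 0.0;
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        dj = std::max(dj, std::fabs(W(i, j) - w12(i)));
        W(i, j) = w12(i);
        W(j, i) = w12(i);
        B(i, j) = beta(i);
      }
      B(j, j) = 0.0;
      dmax = std::max(dmax, dj);
    }
    niter = it + 1;
    if (dmax < thr) { converged = true; break; }
  }
}

static mat theta_from_WB(const mat& S, const mat& W, const mat& B) {
  const uword p = S.n_rows;
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double quad = 0.0;
    for (uword i = 0; i < p; ++i) if (i != j) quad += W(i, j) * B(i, j);
    double tjj = 1.0 / (W(j, j) - quad);
    Theta(j, j) = tjj;
    for (uword i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -B(i, j) * tjj;
  }
  // exact symmetry; keeps the soft-threshold zeros exact
  for (uword j = 0; j < p; ++j)
    for (uword i = j + 1; i < p; ++i) {
      if (Theta(i, j) == 0.0 || Theta(j, i) == 0.0) {
        Theta(i, j) = 0.0; Theta(j, i) = 0.0;
      } else {
        double v = 0.5 * (Theta(i, j) + Theta(j, i));
        Theta(i, j) = v; Theta(j, i) = v;
      }
    }
  return Theta;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      double tol = 1e-7, int maxit = 1000) {
  mat W = S;
  mat B(S.n_rows, S.n_cols, fill::zeros);
  int niter = 0; bool conv = false;
  glasso_core(S, lambda, W, B, tol, maxit, niter, conv);
  mat Theta = theta_from_WB(S, W, B);
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("niter") = niter,
                            Rcpp::Named("converged") = conv);
}

// Warm-started fits along a decreasing penalty path. Returns per-lambda
// precision matrices plus the Gaussian fit term logdet(Theta) - tr(S Theta)
// and the edge count, so penalty selection stays a cheap vector computation.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-7, int maxit = 1000) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  cube Thetas(p, p, L);
  vec fit(L), ecount(L);
  Rcpp::IntegerVector iters(L);
  Rcpp::LogicalVector convs(L);

  mat W = S;
  mat B(p, p, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    int niter = 0; bool conv = false;
    glasso_core(S, lambdas(l), W, B, tol, maxit, niter, conv);
    mat Theta = theta_from_WB(S, W, B);
    Thetas.slice(l) = Theta;
    double sign, ld;
    log_det(ld, sign, Theta);
    fit(l) = ld - trace(S * Theta);
    uword e = 0;
    for (uword j = 0; j < p; ++j)
      for (uword i = j + 1; i < p; ++i)
        if (Theta(i, j) != 0.0) ++e;
    ecount(l) = (double)e;
    iters[l] = niter;
    convs[l] = conv;
  }
  return Rcpp::List::create(Rcpp::Named("Thetas") = Thetas,
                            Rcpp::Named("fit") = fit,
                            Rcpp::Named("edges") = ecount,
                            Rcpp::Named("niter") = iters,
                            Rcpp::Named("converged") = convs);
}
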