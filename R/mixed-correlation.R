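#' Classify a variable as ordinal or continuous
#'
#' A scale is treated as ordinal when it shows fewer than 7 distinct
#' observed values (the conventional cut below which interval-scale
#' treatment of Likert-type scores becomes unsafe), otherwise continuous.
#'
#' @param values observed scores (`NA` ignored).
#' @return `"ordinal"` or `"continuous"`.
#' @export
classify_variable <- function(values) {
  u <- unique(values[!is.na(values)])
  if (length(u) < 2) stop_arg("constant column: cannot classify")
  if (length(u) < 7) "ordinal" else "continuous"
}

# thresholds tau_1 < ... < tau_{K-1} from marginal category proportions
marginal_thresholds <- function(f) {
  cum <- cumsum(f) / sum(f)
  qnorm(cum[-length(cum)])
}

# bivariate standard normal CDF P(X <= a, Y <= b) with correlation rho;
# a, b may be +/- Inf
pbvn <- function(a, b, rho) {
  if (a == -Inf || b == -Inf) return(0)
  if (a == Inf && b == Inf) return(1)
  if (a == Inf) return(pnorm(b))
  if (b == Inf) return(pnorm(a))
  mvtnorm::pmvnorm(upper = c(a, b),
                   corr = matrix(c(1, rho, rho, 1), 2))[1]
}

polychoric_loglik <- function(rho, tab, tx, ty) {
  K <- nrow(tab); L <- ncol(tab)
  ax <- c(-Inf, tx, Inf)
  ay <- c(-Inf, ty, Inf)
  Fm <- matrix(0, K + 1, L + 1)
  for (i in seq_len(K + 1)) {
    for (j in seq_len(L + 1)) {
      Fm[i, j] <- pbvn(ax[i + 0], ay[j + 0], rho)
    }
  }
  # cell probability by inclusion-exclusion over CDF corners
  ll <- 0
  for (i in seq_len(K)) {
    for (j in seq_len(L)) {
      pr <- Fm[i + 1, j + 1] - Fm[i, j + 1] - Fm[i + 1, j] + Fm[i, j]
      if (tab[i, j] > 0) {
        ll <- ll + tab[i, j] * log(max(pr, 1e-12))
      }
    }
  }
  ll
}

#' Polychoric correlation (two-step estimate)
#'
#' Latent bivariate-normal correlation between two ordinal variables.
#' Thresholds are fixed at the inverse standard-normal CDF of the cumulative
#' marginal proportions (step one); the correlation then maximises the
#' bivariate-normal cell-probability log-likelihood over (-0.999, 0.999)
#' (step two).
#'
#' @param x,y ordinal vectors, or `x` may be a contingency `table`/matrix
#'   (then `y` is ignored).
#' @param correct continuity correction added to every cell when the table
#'   contains zero counts (default 0: likelihood left unmodified).
#' @return estimated correlation in (-1, 1).
#' @export
polychoric <- function(x, y = NULL, correct = 0) {
  tab <- if (is.matrix(x) || is.table(x)) {
    unclass(as.matrix(x))
  } else {
    table(factor(x), factor(y))
  }
  tab <- tab + if (any(tab == 0)) correct else 0
  rs <- rowSums(tab); cs <- colSums(tab)
  if (sum(rs > 0) < 2 || sum(cs > 0) < 2) {
    stop_arg("degenerate contingency table: need >= 2 categories per margin")
  }
  tab <- tab[rs > 0, cs > 0, drop = FALSE]
  tx <- marginal_thresholds(rowSums(tab))
  ty <- marginal_thresholds(colSums(tab))
  opt <- optimize(polychoric_loglik, c(-0.999, 0.999), maximum = TRUE,
                  tab = tab, tx = tx, ty = ty, tol = 1e-6)
  rho <- opt$maximum
  if (abs(rho) > 0.998) {
    warning("polychoric estimate at boundary; clamped to +/-0.998")
    rho <- sign(rho) * 0.998
  }
  rho
}

polyserial_loglik <- function(rho, z, ki, tau) {
  s <- sqrt(1 - rho^2)
  a <- c(-Inf, tau, Inf)
  up <- pnorm((a[ki + 1] - rho * z) / s)
  lo <- pnorm((a[ki] - rho * z) / s)
  sum(log(pmax(up - lo, 1e-12)))
}

#' Polyserial correlation (two-step estimate)
#'
#' Latent correlation between a continuous and an ordinal variable:
#' ordinal thresholds come from the marginal proportions; the correlation
#' maximises the conditional likelihood of the observed categories given
#' the standardised continuous score.
#'
#' @param x continuous vector.
#' @param y ordinal vector (>= 2 observed categories).
#' @return estimated correlation in (-1, 1).
#' @export
polyserial <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (sd(x) == 0) stop_arg("continuous variable is constant")
  f <- factor(y)
  if (nlevels(f) < 2) stop_arg("ordinal variable needs >= 2 categories")
  tau <- marginal_thresholds(as.numeric(table(f)))
  z <- (x - mean(x)) / sd(x)
  ki <- as.integer(f)
  opt <- optimize(polyserial_loglik, c(-0.999, 0.999), maximum = TRUE,
                  z = z, ki = ki, tau = tau, tol = 1e-6)
  rho <- opt$maximum
  if (abs(rho) > 0.998) {
    warning("polyserial estimate at boundary; clamped to +/-0.998")
    rho <- sign(rho) * 0.998
  }
  rho
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Eigenvalue clipping at `tol` followed by rescaling to unit diagonal.
#' A no-op when the smallest eigenvalue already exceeds `tol`.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param tol eigenvalue floor (default 1e-8).
#' @return list: `R` (repaired), `repaired` flag, `min_eigenvalue_before`,
#'   `max_change` (largest entrywise absolute change).
#' @export
nearest_pd_correlation <- function(R, tol = 1e-8) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  min_ev <- min(e$values)
  if (min_ev >= tol) {
    return(list(R = R, repaired = FALSE, min_eigenvalue_before = min_ev,
                max_change = 0))
  }
  ev <- pmax(e$values, tol)
  R2 <- e$vectors %*% diag(ev) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2 <- (R2 + t(R2)) / 2
  dimnames(R2) <- dimnames(R)
  list(R = R2, repaired = TRUE, min_eigenvalue_before = min_ev,
       max_change = max(abs(R2 - R)))
}

#' Mixed-type correlation matrix for a set of scales
#'
#' Builds the correlation matrix feeding the graphical lasso: Pearson for
#' continuous-continuous pairs, polyserial for continuous-ordinal, and
#' polychoric for ordinal-ordinal, with each column's type decided by
#' [classify_variable()] (fewer than 7 observed levels = ordinal). The
#' assembled matrix is repaired to the nearest positive semidefinite
#' correlation matrix when pairwise estimation leaves negative eigenvalues.
#'
#' @param table a complete `cohort_table` (run [impute_copy_mean()] first)
#'   or a numeric matrix with scales as columns.
#' @param nodes character vector of scales to include (default: all).
#' @param timepoint which visit to use when `table` is a `cohort_table`.
#' @param method `"auto"` for type-based dispatch, `"pearson"` to force
#'   Pearson throughout (useful in resampling-heavy runs on continuous
#'   margins).
#' @param pd_tol eigenvalue floor for the repair step.
#' @return a `mixed_corr` object: `R`, `method_labels`, `pd_repaired`,
#'   `min_eigenvalue_before`, `nodes`, `n`.
#' @export
mixed_matrix <- function(table, nodes = NULL, timepoint = NULL,
                         method = c("auto", "pearson"), pd_tol = 1e-8) {
  method <- match.arg(method)
  if (inherits(table, "cohort_table")) {
    timepoint <- timepoint %||% table$timepoints[1]
    X <- table$scores[[timepoint]]
  } else {
    X <- as.matrix(table)
  }
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("V%02d", seq_len(ncol(X)))
  }
  nodes <- nodes %||% colnames(X)
  missing_nodes <- setdiff(nodes, colnames(X))
  if (length(missing_nodes)) {
    stop_arg("nodes not in table: ", paste(missing_nodes, collapse = ", "))
  }
  X <- X[, nodes, drop = FALSE]
  if (anyNA(X)) stop_arg("missing values present: impute before correlating")
  p <- ncol(X)
  kinds <- if (method == "pearson") {
    rep("continuous", p)
  } else {
    vapply(seq_len(p), function(k) classify_variable(X[, k]), character(1))
  }

  if (all(kinds == "continuous")) {
    R <- cor(X)
    diag(R) <- 1
    lab <- matrix("pearson", p, p)
    diag(lab) <- ""
    dimnames(R) <- dimnames(lab) <- list(nodes, nodes)
    rep_out <- nearest_pd_correlation(R, tol = pd_tol)
    return(structure(list(R = rep_out$R, method_labels = lab,
                          pd_repaired = rep_out$repaired,
                          min_eigenvalue_before = rep_out$min_eigenvalue_before,
                          max_change = rep_out$max_change,
                          nodes = nodes, n = nrow(X)),
                     class = "mixed_corr"))
  }

  R <- diag(p)
  lab <- matrix("", p, p)
  dimnames(R) <- dimnames(lab) <- list(nodes, nodes)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      pair_kind <- paste(sort(c(kinds[i], kinds[j])), collapse = "-")
      est <- tryCatch(switch(pair_kind,
        "continuous-continuous" = {
          lab[i, j] <- "pearson"
          cor(X[, i], X[, j])
        },
        "continuous-ordinal" = {
          lab[i, j] <- "polyserial"
          if (kinds[i] == "continuous") {
            polyserial(X[, i], X[, j])
          } else {
            polyserial(X[, j], X[, i])
          }
        },
        "ordinal-ordinal" = {
          lab[i, j] <- "polychoric"
          polychoric(X[, i], X[, j])
        }),
        error = function(e) {
          stop_arg(sprintf("correlation failed for pair (%s, %s): %s",
                           nodes[i], nodes[j], conditionMessage(e)))
        })
      R[i, j] <- R[j, i] <- est
      lab[j, i] <- lab[i, j]
    }
  }
  rep_out <- nearest_pd_correlation(R, tol = pd_tol)
  structure(list(R = rep_out$R, method_labels = lab,
                 pd_repaired = rep_out$repaired,
                 min_eigenvalue_before = rep_out$min_eigenvalue_before,
                 max_change = rep_out$max_change,
                 nodes = nodes, n = nrow(X)),
            class = "mixed_corr")
}

#' @export
print.mixed_corr <- function(x, ...) {
  cat(sprintf("<mixed_corr> %d nodes, n = %d, repaired = %s\n",
              length(x$nodes), x$n, x$pd_repaired))
  invisible(x)
}
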