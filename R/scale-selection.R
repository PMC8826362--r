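#' Benjamini-Hochberg step-up adjustment
#'
#' Classic false-discovery-rate adjustment: sort the m p-values, multiply by
#' m/rank, and enforce monotonicity by a cumulative minimum from the largest
#' rank down, capping at 1.
#'
#' @param pvalues numeric vector in \[0, 1\] (`NA` allowed, passed through).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop_arg("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  p <- pvalues[ok]
  m <- length(p)
  if (m) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    out[ok] <- adj
  }
  out
}

classify_strength <- function(abs_rho) {
  ifelse(is.na(abs_rho), NA_character_,
  ifelse(abs_rho >= 0.50, "strong",
  ifelse(abs_rho >= 0.30, "moderate",
  ifelse(abs_rho >= 0.10, "weak", "none"))))
}

#' Spearman screening of all scales against a target scale
#'
#' Computes, per timepoint, the Spearman rank correlation of every other
#' scale with `target`, a two-sided p-value from the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n-2` df, Benjamini-Hochberg
#' adjusted p-values within each timepoint's family of tests, a
#' weak/moderate/strong class per timepoint (|rho| 0.10-0.29 weak,
#' 0.30-0.49 moderate, >= 0.50 strong), and the across-timepoint mean of
#' |rho| used for node selection.
#'
#' @param table a `cohort_table` with at least 2 timepoints.
#' @param target name of the target scale (e.g. the global QoL scale).
#' @param threshold selection threshold on mean |rho| (strict `>`).
#' @return data frame with one row per non-target scale: `rho_<tp>`,
#'   `p_<tp>`, `q_<tp>`, `class_<tp>` per timepoint, `mean_abs_rho`,
#'   `selected`.
#' @export
spearman_screen <- function(table, target, threshold = 0.3) {
  stopifnot(inherits(table, "cohort_table"))
  nm <- scale_names(table)
  if (!target %in% nm) stop_arg("target scale '", target, "' not found")
  others <- setdiff(nm, target)
  out <- data.frame(scale = others, stringsAsFactors = FALSE)
  abs_mat <- matrix(NA_real_, length(others), length(table$timepoints))

  for (ti in seq_along(table$timepoints)) {
    tp <- table$timepoints[ti]
    X <- table$scores[[tp]]
    y <- X[, target]
    rho <- p <- rep(NA_real_, length(others))
    for (j in seq_along(others)) {
      x <- X[, others[j]]
      keep <- !is.na(x) & !is.na(y)
      n <- sum(keep)
      if (n < 4) stop_arg("need n >= 4 complete pairs for scale ", others[j])
      if (length(unique(x[keep])) < 2 || length(unique(y[keep])) < 2) {
        warning("constant column for scale '", others[j],
                "' at ", tp, "; rho undefined")
        next
      }
      r <- cor(x[keep], y[keep], method = "spearman")
      rho[j] <- r
      if (abs(r) < 1) {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        p[j] <- 2 * pt(-abs(tt), df = n - 2)
      } else {
        p[j] <- 0
      }
    }
    out[[paste0("rho_", tp)]] <- rho
    out[[paste0("p_", tp)]] <- p
    out[[paste0("q_", tp)]] <- bh_adjust(p)
    out[[paste0("class_", tp)]] <- classify_strength(abs(rho))
    abs_mat[, ti] <- abs(rho)
  }
  out$mean_abs_rho <- rowMeans(abs_mat)
  out$selected <- !is.na(out$mean_abs_rho) & out$mean_abs_rho > threshold
  out
}

#' Select network nodes from a screening table
#'
#' Keeps the target plus every scale whose across-timepoint mean |rho| with
#' the target strictly exceeds `threshold`, in stable input order.
#'
#' @param rows a data frame with columns `scale` and either `mean_abs_rho`
#'   or at least two `rho_*` columns from which it is computed.
#' @param target target scale name, always included (first).
#' @param threshold strict selection threshold (default 0.3).
#' @return character vector of node names, target first.
#' @export
select_nodes <- function(rows, target, threshold = 0.3) {
  if (!"mean_abs_rho" %in% names(rows)) {
    rho_cols <- grep("^rho_", names(rows), value = TRUE)
    if (length(rho_cols) < 2) {
      stop_arg("`rows` needs mean_abs_rho or >= 2 rho_* columns")
    }
    rows$mean_abs_rho <- rowMeans(abs(as.matrix(rows[rho_cols])))
  }
  keep <- !is.na(rows$mean_abs_rho) & rows$mean_abs_rho > threshold
  c(target, setdiff(rows$scale[keep], target))
}

#' Published univariate Spearman correlations with global QoL
#'
#' The 23 scale-level Spearman correlations of EORTC QLQ-C30/BR23 scales and
#' the 13-item depression score with global QoL at baseline and 12 months,
#' as published for an early breast cancer rehabilitation cohort (n = 487).
#' Used as the worked example for the node-selection rule.
#'
#' @return data frame: `scale`, `rho_M0`, `rho_M12`, significance stars.
#' @export
published_gqol_correlations <- function() {
  path <- system.file("extdata", "gqol_spearman_published.csv",
                      package = "qolnet", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
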