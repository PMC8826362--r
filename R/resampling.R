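subset_cohort <- function(table, idx) {
  table$subjects <- table$subjects[idx]
  table$scores <- lapply(table$scores, function(m) m[idx, , drop = FALSE])
  table$miss <- lapply(table$miss, function(m) m[idx, , drop = FALSE])
  table
}

net_stat_vectors <- function(net) {
  cent <- centralities(net)
  list(edges = upper_tri_vec(net$weights),
       strength = cent$strength,
       closeness = cent$closeness,
       betweenness = cent$betweenness)
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Case-dropping bootstrap stability of a network
#'
#' For each proportion in the grid, repeatedly drops `ceiling(prop * n)`
#' subjects without replacement (a subject's two visits always travel
#' together), re-estimates the network with the identical
#' correlation + EBIC-glasso pipeline, and correlates the resampled
#' edge-weight vector (and node strength / closeness / betweenness vectors)
#' with the full-sample ones. The CS-coefficient is the largest proportion
#' at which at least `cs_prob` of replicates keep a correlation of at least
#' `cs_cor` with the original.
#'
#' @param table complete `cohort_table`.
#' @param config a [pipeline_config()].
#' @param timepoint visit to analyse.
#' @param nodes scales to include.
#' @param proportions drop-proportion grid (default `config$cs_grid`).
#' @param B replicates per proportion (default `config$bootstrap_B`;
#'   a warning is issued below 100).
#' @param seed RNG seed (default `config$seed`).
#' @return a `stability_report`: `correlations` (long data frame:
#'   proportion, replicate, statistic, correlation), `cs` (per-statistic
#'   CS-coefficients), `failures`, `B`, plus the full-sample network.
#' @export
case_drop_bootstrap <- function(table, config = pipeline_config(),
                                timepoint = NULL, nodes = NULL,
                                proportions = NULL, B = NULL, seed = NULL) {
  B <- B %||% config$bootstrap_B
  seed <- seed %||% config$seed
  proportions <- proportions %||% config$cs_grid
  if (B < 100) warning("B < 100: stability quantiles are crude")
  timepoint <- timepoint %||% table$timepoints[1]
  full <- fit_network(table, config, timepoint, nodes)
  ref <- net_stat_vectors(full)
  n <- length(table$subjects)
  stats <- names(ref)

  rows <- list()
  failures <- 0L
  total <- 0L
  for (prop in proportions) {
    keep_n <- n - ceiling(prop * n)
    for (b in seq_len(B)) {
      total <- total + 1L
      idx <- with_seed(child_seed(seed, total), sample.int(n, keep_n))
      sub <- subset_cohort(table, idx)
      net <- tryCatch(fit_network(sub, config, timepoint, nodes),
                      error = function(e) NULL)
      if (is.null(net)) {
        failures <- failures + 1L
        if (failures > max(1, 0.05 * length(proportions) * B)) {
          stop("more than 5% of stability replicates failed")
        }
        next
      }
      v <- net_stat_vectors(net)
      for (s in stats) {
        rows[[length(rows) + 1L]] <- data.frame(
          proportion = prop, replicate = b, statistic = s,
          correlation = if (prop == 0) 1 else safe_cor(ref[[s]], v[[s]]))
      }
    }
  }
  correlations <- do.call(rbind, rows)
  cs <- do.call(rbind, lapply(stats, function(s) {
    cs_from_curve(correlations[correlations$statistic == s, ],
                  cor_threshold = config$cs_cor, prob = config$cs_prob,
                  statistic = s)
  }))
  structure(list(correlations = correlations, cs = cs, B = B,
                 proportions = proportions, failures = failures,
                 network = full, seed = seed),
            class = "stability_report")
}

cs_from_curve <- function(curve, cor_threshold, prob, statistic) {
  props <- sort(unique(curve$proportion))
  ok <- vapply(props, function(pp) {
    r <- curve$correlation[curve$proportion == pp]
    r <- r[!is.na(r)]
    length(r) > 0 && mean(r >= cor_threshold) >= prob
  }, logical(1))
  passing <- props[ok]
  below <- length(passing) == 0
  cs <- if (below) 0 else max(passing)
  data.frame(statistic = statistic, cs = cs, below_grid = below,
             cor_threshold = cor_threshold, prob = prob)
}

#' Recompute CS-coefficients at a different correlation threshold
#'
#' @param report a `stability_report`.
#' @param cor_threshold correlation threshold (e.g. 0.5 or 0.7).
#' @param prob probability level (default 0.95).
#' @return per-statistic CS data frame.
#' @export
cs_coefficient <- function(report, cor_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(report, "stability_report"))
  stats <- unique(report$correlations$statistic)
  do.call(rbind, lapply(stats, function(s) {
    cs_from_curve(report$correlations[report$correlations$statistic == s, ],
                  cor_threshold, prob, s)
  }))
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> B = %d per proportion, %d failures\n",
              x$B, x$failures))
  print(x$cs, row.names = FALSE)
  invisible(x)
}

#' Nonparametric bootstrap of edge weights
#'
#' Resamples subjects with replacement `B` times, reruns the
#' correlation + EBIC-glasso pipeline, and reports 2.5%/97.5% quantile
#' confidence intervals per edge. The replicate edge-weight and
#' node-strength draws are retained for [difference_tests()].
#'
#' @inheritParams case_drop_bootstrap
#' @return an `edge_bootstrap`: `ci` (data frame edge/estimate/lower/upper),
#'   `boot_edges` (B x n_pairs), `boot_strength` (B x p), `failures`, `B`,
#'   and the full-sample network.
#' @export
edge_ci_bootstrap <- function(table, config = pipeline_config(),
                              timepoint = NULL, nodes = NULL,
                              B = NULL, seed = NULL) {
  B <- B %||% config$bootstrap_B
  seed <- seed %||% config$seed
  if (B < 100) warning("B < 100: bootstrap quantiles are crude")
  timepoint <- timepoint %||% table$timepoints[1]
  full <- fit_network(table, config, timepoint, nodes)
  n <- length(table$subjects)
  est <- upper_tri_vec(full$weights)
  labels <- upper_tri_labels(full$nodes)
  boot_edges <- matrix(NA_real_, B, length(est))
  boot_strength <- matrix(NA_real_, B, length(full$nodes),
                          dimnames = list(NULL, full$nodes))
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(child_seed(seed, b), sample.int(n, n, replace = TRUE))
    net <- tryCatch(fit_network(subset_cohort(table, idx), config,
                                timepoint, nodes),
                    error = function(e) NULL)
    if (is.null(net)) {
      failures <- failures + 1L
      if (failures > max(1, 0.05 * B)) {
        stop("more than 5% of bootstrap replicates failed")
      }
      next
    }
    boot_edges[b, ] <- upper_tri_vec(net$weights)
    boot_strength[b, ] <- rowSums(abs(net$weights))
  }
  ok <- !is.na(boot_edges[, 1])
  qs <- apply(boot_edges[ok, , drop = FALSE], 2, quantile,
              probs = c(0.025, 0.975))
  structure(list(
    ci = data.frame(edge = labels, estimate = est,
                    lower = qs[1, ], upper = qs[2, ], row.names = NULL),
    boot_edges = boot_edges[ok, , drop = FALSE],
    boot_strength = boot_strength[ok, , drop = FALSE],
    edge_labels = labels, B = B, failures = failures, network = full,
    seed = seed
  ), class = "edge_bootstrap")
}

#' Bootstrapped difference tests for edges and node strengths
#'
#' Two edge weights (or two node strengths) differ significantly when the
#' central 95% bootstrap quantile interval of their difference excludes
#' zero. No multiple-testing correction is applied (by design: the
#' procedure is descriptive).
#'
#' @param boot an [edge_ci_bootstrap()] result.
#' @param level interval level (default 0.95).
#' @return list of two symmetric logical matrices: `edges` (n_pairs x
#'   n_pairs) and `strength` (p x p).
#' @export
difference_tests <- function(boot, level = 0.95) {
  stopifnot(inherits(boot, "edge_bootstrap"))
  a <- (1 - level) / 2
  sig_mat <- function(draws, labels) {
    k <- ncol(draws)
    sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
    for (i in seq_len(k - 1)) {
      d <- draws[, (i + 1):k, drop = FALSE] - draws[, i]
      qs <- apply(d, 2, quantile, probs = c(a, 1 - a))
      s <- qs[1, ] > 0 | qs[2, ] < 0
      sig[i, (i + 1):k] <- s
      sig[(i + 1):k, i] <- s
    }
    sig
  }
  list(edges = sig_mat(boot$boot_edges, boot$edge_labels),
       strength = sig_mat(boot$boot_strength, colnames(boot$boot_strength)))
}
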