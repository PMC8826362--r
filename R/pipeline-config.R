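#' Pipeline configuration
#'
#' Collects every tunable setting of the network pipeline with defaults at
#' the conventional published values: selection threshold 0.3 on mean |rho|,
#' EBIC gamma 0.5, 100-point lambda path with min ratio 0.01, 1000
#' bootstraps, 5000 permutations, univariate alpha 0.05, comparison alpha
#' 0.005, display cutoffs 0.05 (network) and 0.04 (difference network).
#'
#' @param target target scale for screening/selection.
#' @param selection_threshold strict mean-|rho| cutoff for node selection.
#' @param correlation `"auto"` (type-dispatched Pearson/polyserial/
#'   polychoric) or `"pearson"`.
#' @param gamma,n_lambda,lambda_min_ratio EBIC-glasso settings.
#' @param glasso_tol convergence tolerance of the glasso sweeps.
#' @param bootstrap_B bootstrap replicates.
#' @param cs_grid case-dropping proportion grid.
#' @param cs_cor,cs_prob CS-coefficient correlation threshold and
#'   probability level.
#' @param permutations,alpha_comparison permutation-test settings.
#' @param alpha_univariate significance level for the univariate screen.
#' @param display_threshold,diff_display_threshold absolute edge-weight
#'   display cutoffs for network exports.
#' @param seed root RNG seed used by seeded stages when none is supplied
#'   explicitly.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(target = "gQoL",
                            selection_threshold = 0.3,
                            correlation = c("auto", "pearson"),
                            gamma = 0.5,
                            n_lambda = 100,
                            lambda_min_ratio = 0.01,
                            glasso_tol = 1e-7,
                            bootstrap_B = 1000,
                            cs_grid = seq(0.05, 0.75, by = 0.05),
                            cs_cor = 0.7,
                            cs_prob = 0.95,
                            permutations = 5000,
                            alpha_comparison = 0.005,
                            alpha_univariate = 0.05,
                            display_threshold = 0.05,
                            diff_display_threshold = 0.04,
                            seed = 1) {
  correlation <- match.arg(correlation)
  stopifnot(selection_threshold >= 0, gamma >= 0, n_lambda >= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            bootstrap_B >= 1, all(cs_grid >= 0), all(cs_grid < 1),
            cs_cor > 0, cs_cor < 1, cs_prob > 0, cs_prob < 1,
            permutations >= 1,
            alpha_comparison > 0, alpha_comparison < 1,
            alpha_univariate > 0, alpha_univariate < 1,
            display_threshold >= 0, diff_display_threshold >= 0)
  structure(list(
    target = target, selection_threshold = selection_threshold,
    correlation = correlation, gamma = gamma, n_lambda = n_lambda,
    lambda_min_ratio = lambda_min_ratio, glasso_tol = glasso_tol, bootstrap_B = bootstrap_B,
    cs_grid = cs_grid, cs_cor = cs_cor, cs_prob = cs_prob,
    permutations = permutations, alpha_comparison = alpha_comparison,
    alpha_univariate = alpha_univariate,
    display_threshold = display_threshold,
    diff_display_threshold = diff_display_threshold, seed = seed
  ), class = "pipeline_config")
}

#' Estimate the partial-correlation network for one timepoint
#'
#' The correlation + EBIC-glasso step used everywhere networks are
#' (re-)estimated: resampling, permutation comparison and the main run all
#' call this, so they share one code path.
#'
#' @param table a complete `cohort_table` (or numeric score matrix).
#' @param config a [pipeline_config()].
#' @param timepoint visit label (when `table` is a `cohort_table`).
#' @param nodes scales to include (default: all columns).
#' @return a `ggm_network`.
#' @export
fit_network <- function(table, config = pipeline_config(),
                        timepoint = NULL, nodes = NULL) {
  S <- mixed_matrix(table, nodes = nodes, timepoint = timepoint,
                    method = config$correlation)
  ebicglasso(S, n = S$n, gamma = config$gamma,
             n_lambda = config$n_lambda,
             lambda_min_ratio = config$lambda_min_ratio,
             tol = config$glasso_tol)
}
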