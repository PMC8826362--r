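#' Scale definition for a questionnaire scale
#'
#' Describes a single quality-of-life scale: its reporting range, whether it
#' behaves as ordinal (fewer than 7 attainable levels, the conventional cut
#' below which a scale is treated as categorical) or continuous, its scoring
#' direction, and — for the synthetic generator — the target mean and SD of
#' its margin on the reporting scale.
#'
#' @param name scale identifier.
#' @param kind `"ordinal"` or `"continuous"`.
#' @param range numeric length-2, reporting-scale minimum and maximum.
#' @param levels for ordinal scales, the number of attainable values
#'   (must be < 7); ignored for continuous scales.
#' @param direction `"higher_better"` or `"higher_worse"`.
#' @param mean,sd target margin mean and SD on the reporting scale used by
#'   [generate_cohort()]; defaults are the range midpoint and one sixth of
#'   the range width.
#' @return a `scale_def` list.
#' @export
scale_definition <- function(name, kind = c("continuous", "ordinal"),
                             range = c(0, 100), levels = NA_integer_,
                             direction = c("higher_better", "higher_worse"),
                             mean = NULL, sd = NULL) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (length(range) != 2 || !(range[1] < range[2])) {
    stop_arg("`range` must be c(min, max) with min < max")
  }
  if (kind == "ordinal") {
    if (is.na(levels) || levels < 2 || levels >= 7) {
      stop_arg("ordinal scales must declare 2 <= levels < 7")
    }
  }
  structure(list(
    name = name, kind = kind, range = as.numeric(range),
    levels = as.integer(levels), direction = direction,
    mean = mean %||% base::mean(range),
    sd = sd %||% (diff(range) / 6)
  ), class = "scale_def")
}

#' Default scale set for the 15-node quality-of-life network
#'
#' The global QoL scale, the five functional scales, fatigue, insomnia, pain,
#' financial difficulties, four breast-module scales and the 13-item
#' depression sum score, with margin means/SDs matching a published early
#' breast cancer cohort at baseline (all symptom-type scales already reversed
#' to higher-is-better). The two single-item scales (insomnia, financial
#' difficulties) are 4-level ordinal; the rest are continuous.
#'
#' @return list of [scale_definition()] objects.
#' @export
default_scale_definitions <- function() {
  cont <- function(name, mean, sd, range = c(0, 100)) {
    scale_definition(name, "continuous", range = range, mean = mean, sd = sd)
  }
  ordi <- function(name, mean, sd) {
    scale_definition(name, "ordinal", range = c(0, 100), levels = 4L,
                     mean = mean, sd = sd)
  }
  list(
    cont("gQoL", 69.9, 19.0),
    cont("physical_functioning", 82.4, 15.7),
    cont("role_functioning", 86.7, 19.2),
    cont("social_functioning", 87.4, 19.4),
    cont("emotional_functioning", 82.4, 17.5),
    cont("cognitive_functioning", 84.6, 19.5),
    cont("fatigue", 72.6, 18.6),
    ordi("insomnia", 69.3, 29.2),
    cont("pain", 83.0, 18.9),
    ordi("financial_difficulties", 88.7, 21.9),
    cont("body_image", 63.7, 27.4),
    cont("future_perspective", 55.0, 28.8),
    cont("systemic_therapy_side_effects", 78.4, 13.8),
    cont("arm_symptoms", 82.0, 18.2),
    cont("depression", 35.4, 3.8, range = c(0, 39))
  )
}

#' Sparse ground-truth precision matrix for simulation
#'
#' Draws a symmetric positive-definite precision matrix with a requested
#' off-diagonal support density. Edge locations are sampled uniformly among
#' the `p(p-1)/2` pairs; target partial-correlation magnitudes are uniform on
#' `weight_range` (positive with probability `prob_positive`, matching the
#' predominantly positive associations seen among quality-of-life scales;
#' the default magnitudes 0.10-0.35 bracket the edge weights reported for
#' real questionnaire networks of this size).
#' Positive definiteness is guaranteed by an eigenvalue shift: the precision
#' is `I - B` (`B` holding the sampled pcor targets off-diagonal), and when
#' its smallest eigenvalue falls below 0.05 the diagonal is inflated, which
#' shrinks all partial correlations by a common factor. The realised values
#' are returned in `true_pcor`; at moderate density they match the sampled
#' targets closely.
#'
#' @param p number of nodes (2-50).
#' @param density fraction of node pairs carrying an edge, in \[0, 1\].
#' @param weight_range magnitude range for the pre-scaling edge weights.
#' @param prob_positive probability an edge's partial correlation is positive.
#' @param seed integer seed; the draw is deterministic given it.
#' @param node_names optional character vector of length `p`.
#' @return a `precision_spec` list with elements `node_names`, `precision`,
#'   `true_pcor`, `density`, `seed`.
#' @export
make_precision_spec <- function(p, density, weight_range = c(0.10, 0.35),
                                prob_positive = 0.85, seed = 1,
                                node_names = NULL) {
  if (p < 2 || p > 50) stop_arg("`p` must be between 2 and 50")
  if (density < 0 || density > 1) stop_arg("`density` must be in [0, 1]")
  node_names <- node_names %||% sprintf("V%02d", seq_len(p))
  n_pairs <- p * (p - 1) / 2
  n_edges <- round(density * n_pairs)

  K <- with_seed(seed, {
    B <- matrix(0, p, p)
    if (n_edges > 0) {
      pairs <- which(upper.tri(B))
      chosen <- sample(pairs, n_edges)
      w <- runif(n_edges, weight_range[1], weight_range[2]) *
        ifelse(runif(n_edges) < prob_positive, 1, -1)
      B[chosen] <- w
    }
    B <- B + t(B)
    # positive partial correlation <=> negative precision off-diagonal
    K <- diag(p) - B
    min_ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (min_ev < 0.05) diag(K) <- diag(K) + (0.05 - min_ev)
    K
  })
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("internal error: constructed precision not SPD")

  d <- sqrt(diag(K))
  pc <- -K / tcrossprod(d)
  diag(pc) <- 0
  dimnames(K) <- dimnames(pc) <- list(node_names, node_names)
  structure(list(node_names = node_names, precision = K, true_pcor = pc,
                 density = density, seed = seed),
            class = "precision_spec")
}

#' Ground-truth precision matrix from an explicit edge list
#'
#' Builds a `precision_spec` from hand-specified partial correlations
#' instead of a random draw: the precision is `I - B` with `B` holding the
#' target values, inflated on the diagonal (eigenvalue shift) if needed for
#' positive definiteness.
#'
#' @param node_names character vector of node names.
#' @param edges data frame with columns `node_i`, `node_j`, `pcor`.
#' @return a `precision_spec`.
#' @export
precision_spec_from_edges <- function(node_names, edges) {
  p <- length(node_names)
  B <- matrix(0, p, p, dimnames = list(node_names, node_names))
  for (r in seq_len(nrow(edges))) {
    i <- edges$node_i[r]; j <- edges$node_j[r]
    if (!(i %in% node_names) || !(j %in% node_names)) {
      stop_arg("edge references unknown node: ", i, " or ", j)
    }
    B[i, j] <- B[j, i] <- edges$pcor[r]
  }
  K <- diag(p) - B
  min_ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (min_ev < 0.05) diag(K) <- diag(K) + (0.05 - min_ev)
  d <- sqrt(diag(K))
  pc <- -K / tcrossprod(d)
  diag(pc) <- 0
  dimnames(K) <- dimnames(pc) <- list(node_names, node_names)
  density <- sum(pc[upper.tri(pc)] != 0) / (p * (p - 1) / 2)
  structure(list(node_names = node_names, precision = K, true_pcor = pc,
                 density = density, seed = NA_integer_),
            class = "precision_spec")
}

#' Reference ground-truth network for the 15-scale cohort
#'
#' A hand-specified sparse partial-correlation structure over the 15
#' default scales, mimicking the strongest associations reported for real
#' quality-of-life networks (a depression/insomnia/body-image mental-health
#' cluster, a physical-functioning/fatigue axis, a pain/arm-symptoms pair,
#' and global QoL as a hub). Its implied marginal correlations with global
#' QoL range from ~0.2 to ~0.64, matching the published univariate
#' screening table in rank order.
#'
#' @return a `precision_spec` over the [default_scale_definitions()] nodes.
#' @export
default_precision_spec <- function() {
  e <- function(i, j, w) data.frame(node_i = i, node_j = j, pcor = w)
  edges <- rbind(
    e("insomnia", "depression", 0.33),
    e("emotional_functioning", "depression", 0.31),
    e("body_image", "depression", 0.23),
    e("future_perspective", "body_image", 0.36),
    e("physical_functioning", "fatigue", 0.30),
    e("role_functioning", "social_functioning", 0.24),
    e("gQoL", "fatigue", 0.25),
    e("gQoL", "depression", 0.22),
    e("gQoL", "social_functioning", 0.20),
    e("gQoL", "emotional_functioning", 0.15),
    e("gQoL", "role_functioning", 0.15),
    e("gQoL", "physical_functioning", 0.12),
    e("gQoL", "body_image", 0.10),
    e("fatigue", "systemic_therapy_side_effects", 0.28),
    e("fatigue", "role_functioning", 0.18),
    e("fatigue", "cognitive_functioning", 0.12),
    e("pain", "role_functioning", 0.25),
    e("pain", "arm_symptoms", 0.32),
    e("pain", "physical_functioning", 0.18),
    e("cognitive_functioning", "emotional_functioning", 0.30),
    e("cognitive_functioning", "physical_functioning", 0.14),
    e("insomnia", "fatigue", 0.20),
    e("gQoL", "insomnia", 0.03),
    e("social_functioning", "fatigue", 0.15),
    e("financial_difficulties", "future_perspective", 0.22),
    e("financial_difficulties", "role_functioning", 0.18),
    e("arm_symptoms", "systemic_therapy_side_effects", 0.20),
    e("systemic_therapy_side_effects", "emotional_functioning", 0.12),
    e("future_perspective", "emotional_functioning", 0.20))
  nodes <- vapply(default_scale_definitions(), `[[`, character(1), "name")
  precision_spec_from_edges(nodes, edges)
}

# mean and SD of clip(mu + sigma * Z, a, b) for standard normal Z
censored_normal_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Fa <- pnorm(al); Fb <- pnorm(be)
  fa <- dnorm(al); fb <- dnorm(be)
  m1 <- a * Fa + b * (1 - Fb) + mu * (Fb - Fa) + sigma * (fa - fb)
  m2 <- a^2 * Fa + b^2 * (1 - Fb) +
    (mu^2 + sigma^2) * (Fb - Fa) + 2 * mu * sigma * (fa - fb) +
    sigma^2 * (al * fa - be * fb)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# pre-clip (mu, sigma) whose censored margin attains the target mean/SD;
# falls back to the naive affine map when the target is unattainable
censored_normal_params <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mo <- censored_normal_moments(par[1], exp(par[2]), a, b)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  mo <- censored_normal_moments(fit$par[1], exp(fit$par[2]), a, b)
  if (abs(mo["mean"] - target_mean) > 0.05 * target_sd ||
      abs(mo["sd"] - target_sd) > 0.05 * target_sd) {
    return(c(mu = target_mean, sigma = target_sd))
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate a paired two-timepoint questionnaire cohort
#'
#' Latent vectors are drawn from the zero-mean Gaussian whose covariance is
#' the inverse of `spec$precision` (rescaled to unit variances), with the two
#' time points coupled through a per-coordinate latent correlation
#' `subject_corr`. Continuous scales are mapped affinely and clipped to the
#' reporting range, with the affine parameters moment-matched so the clipped
#' (censored-normal) margin attains the target mean/SD; ordinal scales are
#' discretised at equal-probability standard-normal thresholds into `levels`
#' equispaced reporting values. Missingness is MCAR at the cell level, except
#' that a subject is never missing the same scale at both time points (so
#' longitudinal imputation always has an anchor). Each subject has their own
#' deterministic RNG stream derived from `seed`, so enlarging `n` does not
#' change earlier subjects' draws.
#'
#' @param spec a [make_precision_spec()] result.
#' @param scale_defs list of [scale_definition()]s, same length/order as
#'   `spec$node_names`.
#' @param n number of subjects (>= 2).
#' @param subject_corr latent correlation between time points, in \[0, 1).
#' @param missing_rate expected fraction of missing cells, in \[0, 1).
#' @param seed integer root seed.
#' @param timepoints labels for the two visits.
#' @param keep_latent if `TRUE`, the latent Gaussian draws are attached as
#'   attribute `"latent"`.
#' @return a `cohort_table`: list with `subjects`, `timepoints`, `scores`
#'   (list of n x p matrices), `miss` (logical masks), `scale_defs`.
#' @export
generate_cohort <- function(spec, scale_defs, n, subject_corr = 0.5,
                            missing_rate = 0.04, seed = 1,
                            timepoints = c("M0", "M12"),
                            keep_latent = FALSE) {
  if (n < 2) stop_arg("`n` must be at least 2")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_arg("`missing_rate` must be in [0, 1)")
  }
  if (subject_corr < 0 || subject_corr >= 1) {
    stop_arg("`subject_corr` must be in [0, 1)")
  }
  p <- length(spec$node_names)
  if (length(scale_defs) != p) {
    stop_arg("`scale_defs` must match the precision spec's node count")
  }
  Sigma <- solve(spec$precision)
  Sigma <- Sigma / tcrossprod(sqrt(diag(Sigma)))
  L <- chol(Sigma)  # upper triangular: z = t(L) %*% iid
  rho <- subject_corr

  Z <- array(NA_real_, c(n, p, 2))
  M <- array(FALSE, c(n, p, 2))
  for (i in seq_len(n)) {
    with_seed(child_seed(seed, i), {
      z0 <- drop(crossprod(L, rnorm(p)))
      e <- drop(crossprod(L, rnorm(p)))
      z1 <- rho * z0 + sqrt(1 - rho^2) * e
      Z[i, , 1] <- z0
      Z[i, , 2] <- z1
      if (missing_rate > 0) {
        for (k in seq_len(p)) {
          repeat {
            u <- runif(2)
            m <- u < missing_rate
            if (!all(m)) break  # keep >= 1 observation per subject-scale
          }
          M[i, k, ] <- m
        }
      }
    })
  }

  names <- vapply(scale_defs, `[[`, character(1), "name")
  # moment-matched pre-clip parameters, one solve per continuous scale
  margin_par <- lapply(scale_defs, function(def) {
    if (def$kind != "continuous") return(NULL)
    censored_normal_params(def$mean, def$sd, def$range[1], def$range[2])
  })
  scores <- list()
  clipped <- 0L
  for (t in 1:2) {
    X <- matrix(NA_real_, n, p, dimnames = list(NULL, names))
    for (k in seq_len(p)) {
      def <- scale_defs[[k]]
      z <- Z[, k, t]
      if (def$kind == "continuous") {
        mp <- margin_par[[k]]
        x <- mp[["mu"]] + mp[["sigma"]] * z
        nclip <- sum(x < def$range[1] | x > def$range[2])
        clipped <- clipped + nclip
        x <- pmin(pmax(x, def$range[1]), def$range[2])
      } else {
        Lv <- def$levels
        thr <- qnorm(seq_len(Lv - 1) / Lv)
        idx <- findInterval(z, thr)  # 0 .. Lv-1
        x <- def$range[1] + diff(def$range) * idx / (Lv - 1)
      }
      x[M[, k, t]] <- NA_real_
      X[, k] <- x
    }
    scores[[timepoints[t]]] <- X
  }

  out <- cohort_table(
    scores = scores,
    miss = list(M[, , 1], M[, , 2]) |> setNames(timepoints),
    scale_defs = scale_defs,
    subjects = sprintf("S%05d", seq_len(n))
  )
  attr(out, "clipped_cells") <- clipped
  attr(out, "clipped_fraction") <- clipped / (2 * n * p)
  if (keep_latent) attr(out, "latent") <- Z
  out
}

#' Construct a cohort table container
#'
#' @param scores named list (one element per timepoint) of n x p score
#'   matrices with scale names as columns; `NA` marks missing.
#' @param miss optional list of logical masks (defaults to `is.na(scores)`).
#' @param scale_defs list of [scale_definition()]s covering the columns.
#' @param subjects character vector of subject ids.
#' @return a `cohort_table` object.
#' @export
cohort_table <- function(scores, miss = NULL, scale_defs, subjects) {
  stopifnot(is.list(scores), length(scores) >= 1)
  tps <- names(scores)
  n <- nrow(scores[[1]])
  cols <- colnames(scores[[1]])
  for (s in scores) stopifnot(nrow(s) == n, identical(colnames(s), cols))
  if (is.null(miss)) miss <- lapply(scores, is.na)
  names(miss) <- tps
  defs <- vapply(scale_defs, `[[`, character(1), "name")
  if (!identical(sort(defs), sort(cols))) {
    stop_arg("scale_defs must cover exactly the score columns")
  }
  scale_defs <- scale_defs[match(cols, defs)]
  for (t in tps) {
    X <- scores[[t]]
    for (k in seq_along(cols)) {
      r <- scale_defs[[k]]$range
      bad <- which(!is.na(X[, k]) & (X[, k] < r[1] - 1e-9 | X[, k] > r[2] + 1e-9))
      if (length(bad)) {
        stop_arg(sprintf("out-of-range values in scale '%s' at %s (rows %s)",
                         cols[k], t, paste(head(bad, 5), collapse = ", ")))
      }
    }
  }
  structure(list(subjects = subjects, timepoints = tps, scores = scores,
                 miss = miss, scale_defs = scale_defs),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects x %d scales x %d timepoints (%s)\n",
              length(x$subjects), length(x$scale_defs),
              length(x$timepoints), paste(x$timepoints, collapse = ", ")))
  mf <- mean(vapply(x$miss, mean, numeric(1)))
  cat(sprintf("  missing cells: %.2f%%\n", 100 * mf))
  invisible(x)
}

scale_names <- function(table) {
  vapply(table$scale_defs, `[[`, character(1), "name")
}

scale_def_for <- function(table, name) {
  table$scale_defs[[match(name, scale_names(table))]]
}
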