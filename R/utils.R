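`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package functions do not perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-subject child seed from a root seed: changing n leaves
# earlier subjects' draws untouched. Kept below 2^31 - 1.
child_seed <- function(root, i) {
  (as.numeric(root) * 1103515245 + i * 12345) %% 2147483647
}

# Vectorize the upper triangle (column-major order, excluding the diagonal).
upper_tri_vec <- function(m) m[upper.tri(m)]

# Labels "a--b" for the upper-triangle vector of a p x p matrix.
upper_tri_labels <- function(nodes) {
  p <- length(nodes)
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "--")
}

stop_arg <- function(...) stop(..., call. = FALSE)
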