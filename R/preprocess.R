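#' Reverse symptom-type scales to higher-is-better orientation
#'
#' Symptom and depression scores are conventionally reflected about the
#' range maximum (`pivot`) so that, like the functioning scales, a higher
#' value means a better state: `reversed = pivot - original`. Applying the
#' same rules twice restores the original table.
#'
#' @param table a `cohort_table`.
#' @param rules data frame with columns `scale` and `pivot` (100 for the
#'   0-100 questionnaire scales, 39 for the 13-item depression sum).
#' @return the reversed `cohort_table`, with `direction` metadata flipped.
#' @export
reverse_scales <- function(table, rules) {
  stopifnot(inherits(table, "cohort_table"),
            all(c("scale", "pivot") %in% names(rules)))
  nm <- scale_names(table)
  unknown <- setdiff(rules$scale, nm)
  if (length(unknown)) {
    stop_arg("unknown scale(s): ", paste(unknown, collapse = ", "))
  }
  for (r in seq_len(nrow(rules))) {
    k <- match(rules$scale[r], nm)
    piv <- rules$pivot[r]
    for (t in table$timepoints) {
      table$scores[[t]][, k] <- piv - table$scores[[t]][, k]
    }
    def <- table$scale_defs[[k]]
    def$direction <- if (def$direction == "higher_better") {
      "higher_worse"
    } else "higher_better"
    def$mean <- piv - def$mean
    table$scale_defs[[k]] <- def
  }
  table
}

#' Longitudinal copyMean imputation
#'
#' Single imputation for repeated questionnaire scores: linear interpolation
#' within a subject, corrected by the shape of the population mean
#' trajectory. For a gap strictly between observations at visits `a` and
#' `b`, the imputed value at visit `t` is the subject's linear interpolation
#' plus `popmean(t) - lin.interp(popmean; a, b)(t)`; leading/trailing gaps
#' anchored at the nearest observed visit `a` get
#' `observed(a) + popmean(t) - popmean(a)`. Population means use observed
#' (never imputed) values only, so the rule is idempotent.
#'
#' A subject with a scale missing at every visit (possible only if the
#' upstream exclusion of non-participating subjects was skipped) receives
#' the population mean trajectory itself; such cells are flagged
#' `"population"` in the imputation log.
#'
#' @param table a `cohort_table` (any number of timepoints >= 2).
#' @param clip if `TRUE` (default) imputed values are clipped to the scale's
#'   declared range; the underlying rule itself is unbounded.
#' @param snap_ordinal if `TRUE` (default) imputed values on ordinal scales
#'   are snapped to the nearest attainable level, so imputation does not
#'   silently turn a few-level scale into a continuous one.
#' @return a complete `cohort_table`; attribute `"imputation_log"` is a data
#'   frame (subject, scale, timepoint, rule, value).
#' @export
impute_copy_mean <- function(table, clip = TRUE, snap_ordinal = TRUE) {
  stopifnot(inherits(table, "cohort_table"))
  tps <- table$timepoints
  Tn <- length(tps)
  if (Tn < 2) stop_arg("copyMean needs at least two timepoints")
  nm <- scale_names(table)
  p <- length(nm)
  n <- length(table$subjects)

  # population mean trajectory per scale from observed values
  popmean <- matrix(NA_real_, Tn, p, dimnames = list(tps, nm))
  for (t in seq_len(Tn)) {
    X <- table$scores[[t]]
    for (k in seq_len(p)) {
      v <- X[!table$miss[[t]][, k], k]
      if (!length(v)) {
        stop_arg(sprintf(
          "scale '%s' has no observed value at %s: population mean undefined",
          nm[k], tps[t]))
      }
      popmean[t, k] <- mean(v)
    }
  }

  log_rows <- list()
  for (k in seq_len(p)) {
    Y <- sapply(seq_len(Tn), function(t) table$scores[[t]][, k])
    Y <- matrix(Y, nrow = n)
    Msk <- sapply(seq_len(Tn), function(t) table$miss[[t]][, k])
    Msk <- matrix(Msk, nrow = n)
    pm <- popmean[, k]
    def <- table$scale_defs[[k]]
    rng <- def$range
    grid <- if (snap_ordinal && def$kind == "ordinal") {
      rng[1] + diff(rng) * (seq_len(def$levels) - 1) / (def$levels - 1)
    } else NULL
    for (i in seq_len(n)) {
      mi <- Msk[i, ]
      if (!any(mi)) next
      obs <- which(!mi)
      for (t in which(mi)) {
        if (length(obs) == 0) {
          val <- pm[t]; rule <- "population"
        } else {
          lo <- obs[obs < t]
          hi <- obs[obs > t]
          if (length(lo) && length(hi)) {
            a <- max(lo); b <- min(hi)
            w <- (t - a) / (b - a)
            subj_lin <- Y[i, a] + (Y[i, b] - Y[i, a]) * w
            pop_lin <- pm[a] + (pm[b] - pm[a]) * w
            val <- subj_lin + pm[t] - pop_lin
            rule <- "interior"
          } else {
            a <- if (length(lo)) max(lo) else min(hi)
            val <- Y[i, a] + pm[t] - pm[a]
            rule <- if (length(lo)) "trailing" else "leading"
          }
        }
        if (clip) val <- min(max(val, rng[1]), rng[2])
        if (!is.null(grid)) val <- grid[which.min(abs(grid - val))]
        Y[i, t] <- val
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          subject = table$subjects[i], scale = nm[k], timepoint = tps[t],
          rule = rule, value = val)
      }
    }
    for (t in seq_len(Tn)) {
      table$scores[[t]][, k] <- Y[, t]
      table$miss[[t]][, k] <- FALSE
    }
  }
  attr(table, "imputation_log") <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(subject = character(), scale = character(),
               timepoint = character(), rule = character(),
               value = numeric())
  }
  table
}

#' Summarise missingness in a cohort table
#'
#' @param table a `cohort_table`.
#' @return data frame with one row per timepoint: fraction of missing scale
#'   cells and the count of subjects missing every scale at that visit.
#' @export
missing_summary <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  rows <- lapply(table$timepoints, function(t) {
    m <- table$miss[[t]]
    data.frame(timepoint = t,
               missing_fraction = mean(m),
               subjects_all_missing = sum(rowSums(!m) == 0))
  })
  do.call(rbind, rows)
}
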