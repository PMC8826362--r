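#' Write a cohort table as tidy CSV plus metadata side-car
#'
#' One row per subject x timepoint; missing cells are written empty. Scale
#' metadata (kind, range, levels, direction) goes to a YAML side-car.
#'
#' @param table a `cohort_table`.
#' @param path CSV output path.
#' @param metadata_path YAML side-car path (default: `path` with
#'   `.meta.yaml` appended).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path,
                             metadata_path = paste0(path, ".meta.yaml")) {
  nm <- scale_names(table)
  rows <- lapply(table$timepoints, function(t) {
    X <- table$scores[[t]]
    df <- data.frame(subject_id = table$subjects, timepoint = t)
    cbind(df, as.data.frame(X))
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, na = "")
  meta <- lapply(table$scale_defs, function(d) {
    list(name = d$name, kind = d$kind, range = d$range,
         levels = if (is.na(d$levels)) NULL else d$levels,
         direction = d$direction, mean = d$mean, sd = d$sd)
  })
  yaml::write_yaml(list(scales = meta), metadata_path)
  invisible(path)
}

#' Read a tidy cohort CSV with its metadata side-car
#'
#' Validates the schema (`subject_id`, `timepoint`, one column per declared
#' scale), rejects duplicate (subject, timepoint) rows and out-of-range
#' values (reporting the offending cells), and builds the missingness mask
#' from empty cells.
#'
#' @param path CSV path.
#' @param metadata_path YAML side-car path.
#' @return a `cohort_table`.
#' @export
read_cohort_csv <- function(path, metadata_path = paste0(path, ".meta.yaml")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "timepoint") %in% names(df))) {
    stop_arg("cohort CSV needs subject_id and timepoint columns")
  }
  meta <- yaml::read_yaml(metadata_path)
  defs <- lapply(meta$scales, function(m) {
    scale_definition(m$name, m$kind, range = unlist(m$range),
                     levels = m$levels %||% NA_integer_,
                     direction = m$direction,
                     mean = m$mean, sd = m$sd)
  })
  nm <- vapply(defs, `[[`, character(1), "name")
  missing_cols <- setdiff(nm, names(df))
  if (length(missing_cols)) {
    stop_arg("CSV lacks scale column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$subject_id, df$timepoint)
  if (anyDuplicated(key)) {
    stop_arg("duplicate (subject, timepoint) rows: ",
             paste(head(key[duplicated(key)], 3), collapse = "; "))
  }
  tps <- unique(df$timepoint)
  subjects <- unique(df$subject_id)
  scores <- list()
  for (t in tps) {
    sub <- df[df$timepoint == t, ]
    X <- matrix(NA_real_, length(subjects), length(nm),
                dimnames = list(NULL, nm))
    X[match(sub$subject_id, subjects), ] <- as.matrix(sub[, nm])
    scores[[t]] <- X
  }
  bad <- character(0)
  for (t in tps) {
    for (k in seq_along(nm)) {
      r <- defs[[k]]$range
      v <- scores[[t]][, k]
      idx <- which(!is.na(v) & (v < r[1] - 1e-9 | v > r[2] + 1e-9))
      if (length(idx)) {
        bad <- c(bad, sprintf("%s/%s row %d (value %g)",
                              t, nm[k], idx, v[idx]))
      }
    }
  }
  if (length(bad)) {
    stop_arg("out-of-range values: ", paste(head(bad, 10), collapse = "; "))
  }
  cohort_table(scores = scores, scale_defs = defs, subjects = subjects)
}

#' Exclusion filter for the analysis roster
#'
#' Removes subjects flagged as having discontinued during the first year
#' and subjects who participated only once, leaving the analysis
#' population.
#'
#' @param roster data frame with columns `subject_id`, `discontinued`
#'   (logical) and `participations` (integer count of completed visits).
#' @return list: `kept` (subject ids), `n_enrolled`, `n_discontinued`,
#'   `n_single_participation`, `n_analyzed`.
#' @export
exclusion_filter <- function(roster) {
  stopifnot(all(c("subject_id", "discontinued", "participations")
                %in% names(roster)))
  disc <- roster$discontinued
  single <- !disc & roster$participations < 2
  kept <- roster$subject_id[!disc & !single]
  list(kept = kept,
       n_enrolled = nrow(roster),
       n_discontinued = sum(disc),
       n_single_participation = sum(single),
       n_analyzed = length(kept))
}

#' Export a network as edge lists and GraphML
#'
#' Always writes the full-precision edge list; additionally writes a
#' "display" edge list filtered at the absolute-weight threshold, and a
#' GraphML file carrying the weights as edge attributes.
#'
#' @param net a `ggm_network` or `diff_network`.
#' @param prefix output path prefix; files `<prefix>_edges.csv`,
#'   `<prefix>_edges_display.csv`, `<prefix>.graphml` are written.
#' @param threshold display cutoff on |weight| (strictly greater-than).
#' @return data frame of the full edge list, invisibly.
#' @export
write_network <- function(net, prefix, threshold = 0.05) {
  W <- net$weights
  nodes <- net$nodes
  idx <- which(upper.tri(W), arr.ind = TRUE)
  el <- data.frame(node_i = nodes[idx[, 1]], node_j = nodes[idx[, 2]],
                   weight = W[upper.tri(W)])
  write.csv(format(el, digits = 17), paste0(prefix, "_edges.csv"),
            row.names = FALSE, quote = FALSE)
  disp <- el[abs(el$weight) > threshold, ]
  write.csv(format(disp, digits = 17), paste0(prefix, "_edges_display.csv"),
            row.names = FALSE, quote = FALSE)
  A <- W
  dimnames(A) <- list(nodes, nodes)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(el)
}

#' Read a network edge-list CSV back into a weight matrix
#'
#' @param path an `_edges.csv` file written by [write_network()].
#' @param nodes optional node ordering; defaults to order of appearance.
#' @return symmetric weight matrix with zero diagonal.
#' @export
read_network_csv <- function(path, nodes = NULL) {
  el <- read.csv(path, stringsAsFactors = FALSE)
  el$node_i <- trimws(el$node_i); el$node_j <- trimws(el$node_j)
  nodes <- nodes %||% unique(c(el$node_i, el$node_j))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(el))) {
    W[el$node_i[r], el$node_j[r]] <- el$weight[r]
    W[el$node_j[r], el$node_i[r]] <- el$weight[r]
  }
  W
}

#' Save / load a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(cfg))`
#' reproduces `cfg` exactly (all parameters are validated again on read).
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full network pipeline
#'
#' Reversal (optional) -> copyMean imputation -> Spearman screen and node
#' selection -> per-timepoint mixed correlation and EBIC-glasso ->
#' centralities and communities -> optional stability bootstrap -> paired
#' permutation comparison. Every stage's output is collected in the
#' returned bundle; when `out_dir` is given the artifacts and a JSON
#' manifest (config, seed, per-stage counts, package version) are written
#' there.
#'
#' @param table a `cohort_table` (possibly with missing cells) or a path
#'   to a cohort CSV.
#' @param config a [pipeline_config()].
#' @param reversal_rules optional data frame for [reverse_scales()].
#' @param stability if `TRUE` run the case-dropping and edge-CI bootstraps
#'   (the slow stages; off by default).
#' @param comparison if `TRUE` (default) run the paired permutation test.
#' @param out_dir optional output directory.
#' @return a list bundle with elements `table` (imputed), `screen`,
#'   `nodes`, `networks`, `centralities`, `communities`, `stability`,
#'   `nct`, `difference`, `edge_correlation`, `manifest`.
#' @export
run_pipeline <- function(table, config = pipeline_config(),
                         reversal_rules = NULL, stability = FALSE,
                         comparison = TRUE, out_dir = NULL) {
  if (is.character(table)) table <- read_cohort_csv(table)
  stopifnot(inherits(table, "cohort_table"))
  if (!is.null(reversal_rules)) {
    table <- reverse_scales(table, reversal_rules)
  }
  miss_before <- missing_summary(table)
  table <- impute_copy_mean(table)

  screen <- spearman_screen(table, config$target,
                            threshold = config$selection_threshold)
  nodes <- select_nodes(screen, config$target, config$selection_threshold)
  if (length(nodes) < 3) {
    stop_arg("node selection left fewer than 3 nodes")
  }

  networks <- lapply(table$timepoints, function(t) {
    fit_network(table, config, t, nodes)
  })
  names(networks) <- table$timepoints
  cents <- lapply(networks, centralities)
  comms <- lapply(networks, detect_communities, seed = config$seed)

  stab <- NULL
  if (stability) {
    stab <- lapply(table$timepoints, function(t) {
      list(case_drop = case_drop_bootstrap(table, config, t, nodes),
           edge_ci = edge_ci_bootstrap(table, config, t, nodes))
    })
    names(stab) <- table$timepoints
  }

  nct <- diffnet <- ecor <- NULL
  if (comparison && length(table$timepoints) == 2) {
    nct <- nct_paired(table, config, nodes)
    diffnet <- difference_network(networks[[1]], networks[[2]],
                                  config$diff_display_threshold)
    ecor <- edge_weight_correlation(networks[[1]], networks[[2]])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("qolnet")),
    config = unclass(config),
    n_subjects = length(table$subjects),
    timepoints = table$timepoints,
    missing_before_imputation = miss_before,
    n_nodes = length(nodes),
    nodes = nodes,
    potential_edges = length(nodes) * (length(nodes) - 1) / 2,
    edge_counts = vapply(networks, `[[`, integer(1), "edge_count"),
    modularity = vapply(comms, `[[`, numeric(1), "Q")
  )
  bundle <- list(table = table, screen = screen, nodes = nodes,
                 networks = networks, centralities = cents,
                 communities = comms, stability = stab, nct = nct,
                 difference = diffnet, edge_correlation = ecor,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(screen, file.path(out_dir, "univariate_screen.csv"),
              row.names = FALSE)
    for (t in table$timepoints) {
      write_network(networks[[t]],
                    file.path(out_dir, paste0("network_", t)),
                    threshold = config$display_threshold)
      write.csv(cents[[t]],
                file.path(out_dir, paste0("centrality_", t, ".csv")),
                row.names = FALSE)
      write.csv(networks[[t]]$ebic_path,
                file.path(out_dir, paste0("ebic_path_", t, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(diffnet)) {
      write_network(diffnet, file.path(out_dir, "difference_network"),
                    threshold = config$diff_display_threshold)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
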