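#' Run the full pipeline on an expression matrix
#'
#' Chains every stage: preprocessing (screen, winsorize, log, feature
#' selection), co-expression graph, rank-difference edge profiles,
#' three-view embedding, kernel fusion, spectral clustering with
#' eigengap-selected (or overridden) cluster count, start-cluster choice and
#' centroid pseudotime with lineage paths.
#'
#' @param X Raw genes x cells matrix.
#' @param config A [scrden_config()].
#' @param blocklists Passed to [screen_genes()].
#' @param start_markers Marker genes identifying the start state (used when
#'   `start_cluster` is NULL).
#' @param start_cluster Explicit start cluster label; overrides markers.
#' @param depth Run only the leading stages: `"preprocess"`, `"network"`,
#'   `"cluster"` or `"trajectory"` (default, everything).
#' @return List of class `scrden_result` with the stage outputs it reached:
#'   `preprocess`, `coexpression` (`stats`, `B0`, `threshold`, `graph`),
#'   `profiles`, `embeddings`, `fused`, `eigengap`, `labels`, `start`,
#'   `model` (with lineage paths), `ordering` (cells sorted by pseudotime,
#'   ties by cell order), and `config`.
#' @export
scrden_run <- function(X, config = scrden_config(), blocklists = NULL,
                       start_markers = NULL, start_cluster = NULL,
                       depth = c("trajectory", "cluster", "network",
                                 "preprocess")) {
  depth <- match.arg(depth)
  pre <- preprocess(X, config, blocklists)
  res <- structure(list(preprocess = pre, config = config),
                   class = "scrden_result")
  if (depth == "preprocess") return(res)
  res <- run_core(res, pre$log_matrix, pre$feature_matrix, config,
                  start_markers, start_cluster, depth)
  res
}

# Stages downstream of preprocessing, entered from the feature matrix so the
# robustness protocol can re-run them on a perturbed log matrix.
run_core <- function(res, log_matrix, E, config, start_markers, start_cluster,
                     depth = "trajectory") {
  ## co-expression graph
  stats <- pearson_matrix(E)
  B0 <- significance_filter(stats$r, stats$p, alpha = config$pearson_alpha,
                            bh_correct = config$bh_correct)
  thr <- if (!is.null(config$hard_threshold_b0)) {
    list(b0 = config$hard_threshold_b0, source = "user", diagnostics = NULL)
  } else {
    choose_hard_threshold(B0, r2_target = config$scale_free_r2)
  }
  graph <- build_coexpression_graph(B0, thr$b0, stats = stats,
                                    diagnostics = thr)
  ## rank-difference edge profiles
  C0 <- rank_within_cells(E)
  ep <- build_edge_profiles(C0, graph)
  ep <- minmax_normalize(ep)
  ep <- filter_top_cv(ep, top_fraction = config$cv_top_fraction,
                      min_keep = config$cv_min_edges)
  res$coexpression <- list(stats = stats, B0 = B0, threshold = thr,
                           graph = graph)
  res$ranks <- C0
  res$profiles <- ep
  if (depth == "network") return(res)

  ## ensemble clustering
  n <- ncol(ep$values)
  emb <- embed_views(ep, seed = config$random_seed)
  k <- min(config$knn_k, n - 1L)
  if (k < config$knn_k)
    message("knn_k clipped to ", k, " (n_cells - 1)")
  views <- lapply(emb[c("pca", "tsne", "umap")], local_scaling_kernel,
                  k = k, mu = config$kernel_mu)
  fused <- fuse_views(views, iters_max = config$snf_iters_max,
                      tol = config$snf_tol)
  eg <- eigengap_cluster_count(fused$E, i_max = config$eigengap_imax,
                               rule = config$eigengap_rule,
                               n_override = config$n_clusters)
  labels <- spectral_cluster(fused$E, eg$p, seed = config$random_seed)
  res$embeddings <- emb
  res$fused <- fused
  res$eigengap <- eg
  res$labels <- labels
  if (depth == "cluster") return(res)

  ## trajectory
  if (is.null(start_cluster)) {
    if (!is.null(start_markers)) {
      start <- choose_start_cluster(log_matrix, labels, start_markers)
      start_cluster <- start$cluster
      res$start <- start
    } else {
      start_cluster <- "1"
      message("no start markers or cluster given; using cluster 1 (largest)")
    }
  }
  model <- cluster_pseudotime(emb$tsne, labels, start_cluster,
                              mode = config$pseudotime_mode)
  model <- derive_lineage_paths(model)
  res$model <- model
  res$ordering <- names(sort(model$cell_T))   # stable: ties keep cell order
  res
}

#' @export
print.scrden_result <- function(x, ...) {
  cat("scrden pipeline result\n")
  pre <- x$preprocess
  cat(sprintf("  genes: %d screened -> %d features; cells: %d\n",
              nrow(pre$report), nrow(pre$feature_matrix),
              ncol(pre$feature_matrix)))
  if (!is.null(x$coexpression))
    cat(sprintf("  co-expression: %d edges (b0 = %g); %d edge profiles kept\n",
                nrow(x$coexpression$graph$edges), x$coexpression$graph$b0,
                nrow(x$profiles$values)))
  if (!is.null(x$labels))
    cat(sprintf("  clusters: %d (%s rule)\n", max(x$labels),
                x$eigengap$rule))
  if (!is.null(x$model)) {
    cat(sprintf("  start cluster: %s; %d lineage path(s)\n",
                x$model$start_cluster, length(x$model$paths)))
    tq <- sort(unique(round(x$model$cluster_T, 2)))
    cat("  cluster pseudotimes:", paste(tq, collapse = " "), "\n")
  }
  invisible(x)
}

#' Robustness protocol under Gaussian perturbation
#'
#' Re-runs the trajectory stages on noise-perturbed copies of the
#' preprocessed (log-scale) matrix and scores each perturbed cell ordering
#' against the unperturbed one with the robust score. Noise is added per
#' gene at `k * sigma_g` for each level `k`, with `n_reps` independent
#' replicates per level.
#'
#' @param X Raw genes x cells matrix.
#' @param config A [scrden_config()].
#' @param start_markers,start_cluster Passed through to the runs.
#' @param noise_levels Perturbation factors. Default from `config`.
#' @param n_reps Replicates per level. Default 5.
#' @return List with `scores` (data frame `noise_level`, `replicate`,
#'   `robust_score`), `mean_scores` (per level), and `baseline` (the
#'   unperturbed `scrden_result`).
#' @export
robustness_protocol <- function(X, config = scrden_config(),
                                start_markers = NULL, start_cluster = NULL,
                                noise_levels = config$noise_levels,
                                n_reps = 5) {
  pre <- preprocess(X, config, blocklists = NULL)
  base <- structure(list(preprocess = pre, config = config),
                    class = "scrden_result")
  base <- run_core(base, pre$log_matrix, pre$feature_matrix, config,
                   start_markers, start_cluster)
  rows <- list()
  for (li in seq_along(noise_levels)) {
    for (rep in seq_len(n_reps)) {
      seed <- config$random_seed + 1000L * li + rep
      lg <- perturb_with_noise(pre$log_matrix, noise_levels[li], seed = seed)
      sel <- select_feature_genes(lg, I = config$intrinsic_mean_min,
                                  entropy_quantile = config$entropy_quantile)
      cfg <- config
      cfg$random_seed <- seed
      run <- structure(list(preprocess = list(log_matrix = lg,
                                              feature_matrix = sel$matrix),
                            config = cfg), class = "scrden_result")
      run <- run_core(run, lg, sel$matrix, cfg, start_markers, start_cluster)
      rows[[length(rows) + 1]] <- data.frame(
        noise_level = noise_levels[li], replicate = rep,
        robust_score = robust_score(base$ordering, run$ordering))
    }
  }
  scores <- do.call(rbind, rows)
  mean_scores <- tapply(scores$robust_score, scores$noise_level, mean)
  list(scores = scores,
       mean_scores = data.frame(noise_level = as.numeric(names(mean_scores)),
                                mean_robust_score = as.numeric(mean_scores)),
       baseline = base)
}

#' Evaluate an inferred trajectory against truth
#'
#' Convenience wrapper computing POS, bubble sort index, Kendall correlation
#' and clustering agreement for a pipeline result given a truth table.
#'
#' @param result A `scrden_result` from [scrden_run()].
#' @param truth Data frame with `cell_id`, `true_time` and optionally
#'   `branch_label` columns (e.g. `sim$truth$cell_info`).
#' @param true_labels Optional reference labeling for ARI/NMI; defaults to
#'   `branch_label` when present.
#' @return Named list of metric values.
#' @export
evaluate_trajectory <- function(result, truth, true_labels = NULL) {
  times <- stats::setNames(truth$true_time, truth$cell_id)
  out <- list(pos = pos_score(result$ordering, times))
  true_order <- truth$cell_id[order(truth$true_time)]
  out$bubble_sort_index <- bubble_sort_index(true_order, result$ordering)
  out$kendall <- kendall_order_cor(true_order, result$ordering)
  if (is.null(true_labels) && !is.null(truth$branch_label))
    true_labels <- stats::setNames(truth$branch_label, truth$cell_id)
  if (!is.null(true_labels)) {
    agr <- clustering_agreement(result$labels, true_labels)
    out$ari <- unname(agr["ari"])
    out$nmi <- unname(agr["nmi"])
  }
  out
}
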