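#' Pipeline configuration
#'
#' Collects every tunable threshold and hyperparameter of the pipeline with
#' its default. Defaults follow the published protocol where one is stated
#' (10% expression fraction, 4-sigma winsorization, p < 0.01 correlation
#' filter, top-1% CV edge filter, k = 30 neighbours, display threshold 0.2,
#' noise levels 5/10/20%); the remainder are documented package choices.
#'
#' @param expression_fraction_min Keep genes expressed (count > 0) in strictly
#'   more than this fraction of cells. Default 0.10.
#' @param sigma_clip Winsorization half-width in per-gene standard deviations.
#'   Default 4.
#' @param intrinsic_mean_min Minimum mean log2 expression `I` a feature gene
#'   must exceed. Default 1.0.
#' @param entropy_quantile Quantile of the residual-entropy score above which
#'   a gene counts as high intrinsic entropy. Default 0.90.
#' @param pearson_alpha Two-sided p-value cutoff for retaining a correlation.
#'   Default 0.01 (raw, uncorrected; see `bh_correct`).
#' @param bh_correct Apply Benjamini-Hochberg to the correlation p-values
#'   before filtering. Default FALSE (the protocol states a raw cut).
#' @param hard_threshold_b0 User override for the co-expression hard
#'   threshold; NULL selects it by scale-free fit.
#' @param scale_free_r2 Minimum R-squared of the log-log degree fit at which a
#'   threshold candidate is accepted. Default 0.80.
#' @param cv_top_fraction Fraction of edge-profile rows kept by the
#'   coefficient-of-variation filter. Default 0.01.
#' @param cv_min_edges Floor on the number of edge rows the pipeline keeps
#'   after CV filtering (the top-fraction rule targets graphs with 1e5-1e6
#'   pairs; small graphs would otherwise be filtered to nothing). Default 50.
#' @param knn_k Neighbourhood size for the local-scaling kernels. Default 30.
#' @param kernel_mu Kernel bandwidth multiplier mu. Default 0.5.
#' @param snf_iters_max Maximum fusion sweeps. Default 20.
#' @param snf_tol Convergence tolerance on the maximum entry change per
#'   fusion sweep. Default 1e-6.
#' @param n_clusters Cluster count override; NULL selects it by eigengap.
#' @param eigengap_imax Largest cluster count considered by the eigengap
#'   search. Default 15.
#' @param eigengap_rule `"max_gap"` (default) takes the index of the largest
#'   eigengap; `"top2_smaller_value"` takes, of the two largest gaps, the
#'   index of the smaller one.
#' @param pseudotime_mode `"normalized_distance"` (default) or `"rank"`; see
#'   [cluster_pseudotime()].
#' @param edge_display_threshold Stage-network edges with weight strictly
#'   below this are discarded. Default 0.2.
#' @param noise_levels Gaussian perturbation factors for the robustness
#'   protocol. Default c(0.05, 0.10, 0.20).
#' @param random_seed Seed used for every stochastic step. Default 1.
#'
#' @return A named list of class `scrden_config`.
#' @examples
#' cfg <- scrden_config(knn_k = 10)
#' cfg$knn_k
#' @export
scrden_config <- function(expression_fraction_min = 0.10,
                          sigma_clip = 4,
                          intrinsic_mean_min = 1.0,
                          entropy_quantile = 0.90,
                          pearson_alpha = 0.01,
                          bh_correct = FALSE,
                          hard_threshold_b0 = NULL,
                          scale_free_r2 = 0.80,
                          cv_top_fraction = 0.01,
                          cv_min_edges = 50,
                          knn_k = 30,
                          kernel_mu = 0.5,
                          snf_iters_max = 20,
                          snf_tol = 1e-6,
                          n_clusters = NULL,
                          eigengap_imax = 15,
                          eigengap_rule = c("max_gap", "top2_smaller_value"),
                          pseudotime_mode = c("normalized_distance", "rank"),
                          edge_display_threshold = 0.2,
                          noise_levels = c(0.05, 0.10, 0.20),
                          random_seed = 1L) {
  cfg <- list(
    expression_fraction_min = expression_fraction_min,
    sigma_clip = sigma_clip,
    intrinsic_mean_min = intrinsic_mean_min,
    entropy_quantile = entropy_quantile,
    pearson_alpha = pearson_alpha,
    bh_correct = isTRUE(bh_correct),
    hard_threshold_b0 = hard_threshold_b0,
    scale_free_r2 = scale_free_r2,
    cv_top_fraction = cv_top_fraction,
    cv_min_edges = cv_min_edges,
    knn_k = as.integer(knn_k),
    kernel_mu = kernel_mu,
    snf_iters_max = as.integer(snf_iters_max),
    snf_tol = snf_tol,
    n_clusters = if (is.null(n_clusters)) NULL else as.integer(n_clusters),
    eigengap_imax = as.integer(eigengap_imax),
    eigengap_rule = match.arg(eigengap_rule),
    pseudotime_mode = match.arg(pseudotime_mode),
    edge_display_threshold = edge_display_threshold,
    noise_levels = noise_levels,
    random_seed = as.integer(random_seed)
  )
  validate_config(cfg)
  class(cfg) <- "scrden_config"
  cfg
}

validate_config <- function(cfg) {
  frac <- function(x, nm) {
    if (!is.numeric(x) || x <= 0 || x >= 1)
      stop(sprintf("'%s' must lie in (0, 1), got %s", nm, format(x)),
           call. = FALSE)
  }
  frac(cfg$expression_fraction_min, "expression_fraction_min")
  frac(cfg$entropy_quantile, "entropy_quantile")
  frac(cfg$pearson_alpha, "pearson_alpha")
  frac(cfg$cv_top_fraction, "cv_top_fraction")
  if (cfg$knn_k < 1L) stop("'knn_k' must be >= 1", call. = FALSE)
  if (cfg$kernel_mu <= 0) stop("'kernel_mu' must be positive", call. = FALSE)
  if (cfg$sigma_clip <= 0) stop("'sigma_clip' must be positive", call. = FALSE)
  if (!is.null(cfg$hard_threshold_b0) &&
      (cfg$hard_threshold_b0 < 0 || cfg$hard_threshold_b0 >= 1))
    stop("'hard_threshold_b0' must lie in [0, 1)", call. = FALSE)
  if (any(cfg$noise_levels <= 0)) stop("noise levels must be positive", call. = FALSE)
  if (is.na(cfg$random_seed)) stop("'random_seed' must be an integer", call. = FALSE)
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a YAML or JSON file of configuration values and merges it over the
#' defaults of [scrden_config()]. Unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `scrden_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(scrden_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(scrden_config, vals)
}

#' @export
print.scrden_config <- function(x, ...) {
  cat("scrden pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "auto" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
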