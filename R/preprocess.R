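#' Default gene-name screening patterns
#'
#' Regular expressions matching mitochondrial, ribosomal and ERCC spike-in
#' gene identifiers for mouse and human nomenclature.
#'
#' @return Character vector of regular expressions.
#' @export
default_screen_patterns <- function() {
  c("^mt-", "^MT-", "^Rps", "^Rpl", "^RPS", "^RPL", "^ERCC-")
}

#' Screen genes by name and expression fraction
#'
#' Removes genes whose identifier matches a screening pattern (mitochondrial,
#' ribosomal, spike-in) or an explicit blocklist, and genes expressed
#' (raw value strictly positive) in no more than `expression_fraction_min`
#' of the cells. The cell set is unchanged.
#'
#' @param X Genes x cells matrix (raw scale).
#' @param blocklists Optional character vector (or list of vectors) of gene
#'   identifiers to drop regardless of expression.
#' @param patterns Name patterns to drop; see [default_screen_patterns()].
#' @param expression_fraction_min Strict lower bound on the fraction of cells
#'   with positive expression. Default 0.10.
#' @return The reduced matrix, with attribute `screen_report`: a data frame
#'   per input gene with its expression fraction and a reason code in
#'   `{screened_name, low_fraction, kept}`.
#' @export
screen_genes <- function(X, blocklists = NULL,
                         patterns = default_screen_patterns(),
                         expression_fraction_min = 0.10) {
  X <- validate_expression_matrix(X)
  genes <- rownames(X)
  block <- unique(unlist(blocklists, use.names = FALSE))
  name_hit <- Reduce(`|`, lapply(patterns, grepl, x = genes), rep(FALSE, length(genes)))
  name_hit <- name_hit | genes %in% block
  frac <- rowMeans(X > 0)
  reason <- ifelse(name_hit, "screened_name",
                   ifelse(frac <= expression_fraction_min, "low_fraction", "kept"))
  keep <- reason == "kept"
  if (!any(keep))
    stop("screen_genes removed every gene; lower 'expression_fraction_min' ",
         "or check the identifier patterns", call. = FALSE)
  out <- X[keep, , drop = FALSE]
  attr(out, "screen_report") <- data.frame(
    gene_id = genes, fraction_cells_expressed = frac, reason = reason,
    stringsAsFactors = FALSE)
  out
}

#' Winsorize outlying expression values per gene
#'
#' Clips each gene's values to `[mu - s*sigma, mu + s*sigma]`, where `mu` and
#' `sigma` are that gene's mean and standard deviation across cells computed
#' on the input, then floors at 0 (expression cannot be negative). Constant
#' genes (`sigma = 0`) are unchanged.
#'
#' @param X Genes x cells matrix.
#' @param sigma_clip Half-width in standard deviations. Default 4.
#' @return Matrix of the same shape, with attribute `n_winsorized` (per-gene
#'   count of clipped entries).
#' @export
winsorize_outliers <- function(X, sigma_clip = 4) {
  mu <- rowMeans(X)
  sg <- apply(X, 1, sd)
  lo <- mu - sigma_clip * sg
  hi <- mu + sigma_clip * sg
  out <- pmin(pmax(X, lo), hi)   # lo/hi recycle down columns: rows are genes
  out <- pmax(out, 0)
  attr(out, "n_winsorized") <- rowSums(X != out)
  out
}

#' Log2 transform with pseudo-count 1
#'
#' Elementwise `log2(x + 1)`, so zeros stay zero and counts of 1 map to 1.
#'
#' @param X Non-negative matrix.
#' @return Transformed matrix.
#' @export
log_transform <- function(X) {
  if (any(X < 0)) stop("log_transform expects non-negative values", call. = FALSE)
  log2(X + 1)
}

#' Select feature genes by intrinsic (excess) fluctuation
#'
#' Separates each gene's fluctuation into the part a pure count-noise model
#' explains and the intrinsic (regulatory) excess, and keeps genes with a
#' high intrinsic score whose mean log expression also exceeds `I`.
#'
#' The technical baseline is a negative binomial with the gene's raw mean
#' `mu` and a single dispersion `size` estimated robustly across genes
#' (median of the per-gene moment estimates `mu^2 / (var - mu)`); on the
#' `log2(x + 1)` scale its variance is approximated by the delta method as
#' `(mu + mu^2 / size) / ((mu + 1) log 2)^2`. The intrinsic score is the
#' log2 ratio of the observed log-scale variance to this baseline: 0 means
#' the gene fluctuates like noise (a constant gene scores lowest), and
#' strongly regulated genes — ramps, switches, branch-specific programs —
#' score high. Genes are kept when their score exceeds the
#' `entropy_quantile` quantile of all scores and their mean log expression
#' exceeds `I`.
#'
#' @param X Genes x cells matrix on the log scale (`log2(x + 1)` of the
#'   winsorized counts).
#' @param I Minimum mean log expression; a human-selected, data-dependent
#'   threshold. Default 1.0.
#' @param entropy_quantile Score quantile acting as the cutoff. Default 0.90.
#' @return List with `matrix` (the reduced genes x cells matrix) and
#'   `report`, a per-gene data frame (`mean_log_expression`, `var_log`,
#'   `technical_var`, `intrinsic_score`, `kept`, `reason` in
#'   `{low_intrinsic, kept}`).
#' @export
select_feature_genes <- function(X, I = 1.0, entropy_quantile = 0.90) {
  means <- rowMeans(X)
  var_log <- apply(X, 1, var)
  raw <- 2^X - 1
  mu <- rowMeans(raw)
  var_raw <- apply(raw, 1, var)
  size <- nb_global_size(mu, var_raw)
  tech <- (mu + mu^2 / size) / ((mu + 1) * log(2))^2
  score <- log2(pmax(var_log, 1e-12) / pmax(tech, 1e-12))
  cutoff <- quantile(score, entropy_quantile, names = FALSE)
  keep <- score > cutoff & means > I
  report <- data.frame(
    gene_id = rownames(X), mean_log_expression = means, var_log = var_log,
    technical_var = tech, intrinsic_score = score, kept = keep,
    reason = ifelse(keep, "kept", "low_intrinsic"), stringsAsFactors = FALSE)
  if (sum(keep) < 10)
    stop(sprintf(paste0("only %d feature genes survive (need >= 10); lower the ",
                        "mean threshold I (= %g) or the score quantile (= %g)"),
                 sum(keep), I, entropy_quantile), call. = FALSE)
  list(matrix = X[keep, , drop = FALSE], report = report)
}

# Global NB dispersion (size) from per-gene moment estimates; genes at or
# below the Poisson line contribute no estimate. Capped so the baseline
# degrades gracefully to Poisson when nothing is overdispersed.
nb_global_size <- function(mu, var_raw) {
  over <- var_raw > mu & mu > 0
  if (!any(over)) return(1e8)
  min(median(mu[over]^2 / (var_raw[over] - mu[over])), 1e8)
}

#' Run the full preprocessing chain
#'
#' Name/fraction screening, 4-sigma winsorization, `log2(x+1)` transform and
#' residual-entropy feature selection, in that order.
#'
#' @param X Raw genes x cells matrix.
#' @param config A [scrden_config()].
#' @param blocklists Passed to [screen_genes()].
#' @return List with `log_matrix` (all screened genes, log scale — used for
#'   marker scoring), `feature_matrix` (feature genes only), and `report`
#'   combining the per-gene QC of all steps (reason codes partition the input
#'   genes into `screened_name`, `low_fraction`, `low_intrinsic`, `kept`).
#' @export
preprocess <- function(X, config = scrden_config(), blocklists = NULL) {
  scr <- screen_genes(X, blocklists = blocklists,
                      expression_fraction_min = config$expression_fraction_min)
  screen_report <- attr(scr, "screen_report")
  win <- winsorize_outliers(scr, sigma_clip = config$sigma_clip)
  n_wins <- attr(win, "n_winsorized")
  lg <- log_transform(win)
  attr(lg, "n_winsorized") <- NULL      # bookkeeping lives in the report
  attr(lg, "screen_report") <- NULL
  sel <- select_feature_genes(lg, I = config$intrinsic_mean_min,
                              entropy_quantile = config$entropy_quantile)
  report <- screen_report
  report$n_winsorized <- 0L
  report$n_winsorized[match(names(n_wins), report$gene_id)] <- n_wins
  idx <- match(sel$report$gene_id, report$gene_id)
  report$mean_log_expression <- NA_real_
  report$intrinsic_score <- NA_real_
  report$mean_log_expression[idx] <- sel$report$mean_log_expression
  report$intrinsic_score[idx] <- sel$report$intrinsic_score
  report$reason[idx] <- sel$report$reason
  list(log_matrix = lg, feature_matrix = sel$matrix, report = report)
}
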