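#' Pearson correlation and p-value matrices between genes
#'
#' Computes the signed Pearson correlation between every pair of genes across
#' cells, with two-sided p-values from the t distribution with `n - 2`
#' degrees of freedom. Genes with zero variance are flagged and assigned
#' correlation 0 / p-value 1 against all other genes.
#'
#' @param E Genes x cells matrix (feature-selected, log scale).
#' @return List with `r` (signed correlations, unit diagonal), `p`
#'   (p-values, zero diagonal), `n_cells`, and `zero_variance` (logical per
#'   gene).
#' @export
pearson_matrix <- function(E) {
  n <- ncol(E)
  if (n < 3) stop("pearson_matrix needs at least 3 cells", call. = FALSE)
  zv <- apply(E, 1, sd) == 0
  R <- suppressWarnings(cor(t(E)))
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  P[abs(R) >= 1] <- 0
  if (any(zv)) {
    R[zv, ] <- 0; R[, zv] <- 0
    P[zv, ] <- 1; P[, zv] <- 1
  }
  diag(R) <- 1
  diag(P) <- 0
  list(r = R, p = P, n_cells = n, zero_variance = zv)
}

#' Mask insignificant correlations and take absolute values
#'
#' Sets correlations with `p >= alpha` to 0, then takes absolute values,
#' giving the non-negative matrix from which the co-expression graph is
#' thresholded. When `bh_correct` is TRUE the p-values are
#' Benjamini-Hochberg adjusted over the upper triangle first. The diagonal is
#' set to 0 (self-correlations carry no edge information).
#'
#' @param R Signed correlation matrix.
#' @param P Matching p-value matrix.
#' @param alpha Significance cutoff. Default 0.01.
#' @param bh_correct Adjust p-values before masking. Default FALSE.
#' @return Symmetric non-negative matrix `B0` with zero diagonal.
#' @export
significance_filter <- function(R, P, alpha = 0.01, bh_correct = FALSE) {
  stopifnot(all(dim(R) == dim(P)))
  if (bh_correct) {
    ut <- upper.tri(P)
    adj <- p.adjust(P[ut], method = "BH")
    P[ut] <- adj
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  B0 <- abs(R)
  B0[P >= alpha] <- 0
  diag(B0) <- 0
  B0
}

#' Choose the co-expression hard threshold by scale-free fit
#'
#' For each candidate threshold `tau` the unweighted graph `{b_ij > tau}` is
#' formed and the fit of its degree distribution to a power law is scored:
#' degrees are log-binned (10 bins over the occupied degree range, genes of
#' degree 0 excluded), and `log10 p(k)` is regressed on `log10 k`. As in
#' standard practice the fit is balanced against connectivity: candidates
#' whose graph keeps fewer than `min_node_frac` of the genes connected or
#' whose mean degree drops below `min_mean_degree` are inadmissible (a
#' threshold that shatters the network fits nothing). The chosen threshold
#' is the smallest admissible candidate whose R-squared reaches
#' `r2_target`; if none reaches it, the admissible candidate with the
#' largest R-squared (falling back to all candidates when none is
#' admissible).
#'
#' @param B0 Symmetric non-negative matrix from [significance_filter()].
#' @param candidate_grid Thresholds to score. Default `seq(0.10, 0.95, 0.05)`.
#' @param r2_target Acceptance level for the fit. Default 0.80.
#' @param nbins Number of log-spaced degree bins. Default 10.
#' @param min_node_frac Minimum fraction of genes that must stay connected.
#'   Default 0.5.
#' @param min_mean_degree Minimum mean degree over all genes. Default 3.
#' @return List with `b0`, `source = "auto"`, and `diagnostics`: a data frame
#'   of `tau`, `n_edges`, `node_frac`, `mean_degree`, `r2`, `admissible`.
#' @export
choose_hard_threshold <- function(B0, candidate_grid = seq(0.10, 0.95, by = 0.05),
                                  r2_target = 0.80, nbins = 10,
                                  min_node_frac = 0.5, min_mean_degree = 3) {
  stopifnot(isSymmetric(unname(B0)), all(B0 >= 0))
  diag(B0) <- 0
  if (length(candidate_grid) == 1)      # nothing to select between
    return(list(b0 = candidate_grid, source = "auto", diagnostics = NULL))
  m <- nrow(B0)
  diagnostics <- data.frame(tau = candidate_grid, n_edges = NA_integer_,
                            node_frac = NA_real_, mean_degree = NA_real_,
                            r2 = NA_real_, admissible = FALSE)
  for (i in seq_along(candidate_grid)) {
    A <- B0 > candidate_grid[i]
    k <- colSums(A)
    diagnostics$n_edges[i] <- sum(A) / 2
    diagnostics$node_frac[i] <- mean(k > 0)
    diagnostics$mean_degree[i] <- mean(k)
    diagnostics$r2[i] <- scale_free_r2(k[k > 0], nbins)
  }
  diagnostics$admissible <- !is.na(diagnostics$r2) &
    diagnostics$node_frac >= min_node_frac &
    diagnostics$mean_degree >= min_mean_degree
  ok <- diagnostics$admissible
  if (!any(!is.na(diagnostics$r2)))
    stop("degree distribution degenerate at every candidate threshold; ",
         "try a grid with lower values", call. = FALSE)
  if (!any(ok)) ok <- !is.na(diagnostics$r2)
  hit <- ok & diagnostics$r2 >= r2_target
  b0 <- if (any(hit)) {
    candidate_grid[which(hit)[1]]
  } else {
    candidate_grid[ok][which.max(diagnostics$r2[ok])]
  }
  list(b0 = b0, source = "auto", diagnostics = diagnostics)
}

# R-squared of log10 p(k) ~ log10 k over log-spaced degree bins.
scale_free_r2 <- function(k, nbins) {
  if (length(k) < 3 || length(unique(k)) < 3) return(NA_real_)
  lk <- log10(k)
  brk <- seq(min(lk), max(lk), length.out = nbins + 1)
  brk[length(brk)] <- brk[length(brk)] + 1e-9
  bin <- findInterval(lk, brk, rightmost.closed = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tabulate(bin, nbins) / length(k)
  pk <- pk[as.integer(names(dk))]
  use <- pk > 0
  if (sum(use) < 3) return(NA_real_)
  fit <- lm(log10(pk[use]) ~ log10(dk[use]))
  summary(fit)$r.squared
}

#' Build the gene co-expression graph
#'
#' Retains an edge for every unordered gene pair with `b_ij > b0` (strict
#' inequality); the node set is exactly the genes incident to a retained
#' edge, so isolated genes are excluded.
#'
#' @param B0 Symmetric non-negative matrix from [significance_filter()].
#' @param b0 Hard threshold in `[0, 1)`.
#' @param stats Optional result of [pearson_matrix()] supplying the signed
#'   `r` and `p` attributes per edge.
#' @param diagnostics Optional threshold-selection diagnostics to store.
#' @return Object of class `coexpression_graph`: list with `edges` (data
#'   frame `gene_a`, `gene_b`, `weight` = `abs_r`, plus `r`, `p` when
#'   `stats` is given), `genes`, `b0`, `diagnostics`.
#' @export
build_coexpression_graph <- function(B0, b0, stats = NULL, diagnostics = NULL) {
  if (b0 < 0 || b0 >= 1) stop("'b0' must lie in [0, 1)", call. = FALSE)
  diag(B0) <- 0
  idx <- which(upper.tri(B0) & B0 > b0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("no edges survive the hard threshold b0 = ", b0, call. = FALSE)
  genes <- rownames(B0)
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      weight = B0[idx], stringsAsFactors = FALSE)
  if (!is.null(stats)) {
    edges$r <- stats$r[idx]
    edges$abs_r <- abs(edges$r)
    edges$p <- stats$p[idx]
  }
  structure(list(edges = edges, genes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 b0 = b0, diagnostics = diagnostics),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf("coexpression_graph: %d genes, %d edges (b0 = %g)\n",
              length(x$genes), nrow(x$edges), x$b0))
  invisible(x)
}
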