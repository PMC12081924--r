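#' Rank genes within each cell
#'
#' Replaces each cell's expression values with their ascending ranks: the
#' lowest-expressed gene gets rank 1 and the highest rank `m`. Ties are
#' broken by gene (row) order — ordinal ranks — so every column is a
#' permutation of `1..m` and ranks stay positive integers.
#'
#' Because only within-cell order matters, the result is invariant under any
#' strictly monotone transform of a cell's values (log vs raw gives the same
#' ranks), which is what makes the downstream features robust to dropout and
#' scale.
#'
#' @param E Genes x cells matrix (feature-selected).
#' @return Integer matrix of the same shape, attribute `tie_policy =
#'   "ordinal"`.
#' @export
rank_within_cells <- function(E) {
  out <- apply(E, 2, rank, ties.method = "first")
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(E)
  attr(out, "tie_policy") <- "ordinal"
  out
}

#' Build raw rank-difference edge profiles
#'
#' For every edge of the co-expression graph, records in each cell the rank
#' of the first endpoint minus the rank of the second. The stored orientation
#' is fixed as (smaller row index, larger row index) of the rank matrix, so
#' profiles are reproducible; swapping an edge's orientation negates its row.
#'
#' @param C0 Rank matrix from [rank_within_cells()].
#' @param graph A `coexpression_graph` (or any list with an `$edges` data
#'   frame holding `gene_a`, `gene_b`).
#' @return Object of class `edge_profiles`: list with `values` (edges x
#'   cells, row names `"geneA|geneB"`), `edges` (oriented pair table),
#'   `state = "raw"`.
#' @export
build_edge_profiles <- function(C0, graph) {
  edges <- if (is.data.frame(graph)) graph else graph$edges
  ia <- match(edges$gene_a, rownames(C0))
  ib <- match(edges$gene_b, rownames(C0))
  if (anyNA(ia) || anyNA(ib)) {
    missing <- unique(c(edges$gene_a[is.na(ia)], edges$gene_b[is.na(ib)]))
    stop("edge endpoint(s) missing from the rank matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  swap <- ia > ib
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  values <- C0[ia, , drop = FALSE] - C0[ib, , drop = FALSE]
  gene_a <- rownames(C0)[ia]
  gene_b <- rownames(C0)[ib]
  rownames(values) <- paste(gene_a, gene_b, sep = "|")
  structure(list(values = values,
                 edges = data.frame(gene_a = gene_a, gene_b = gene_b,
                                    stringsAsFactors = FALSE),
                 state = "raw"),
            class = "edge_profiles")
}

#' Min-max normalize edge profiles per cell
#'
#' Rescales each cell's column of rank differences to `[0, 1]` by subtracting
#' the column minimum and dividing by the column range, damping the effect of
#' extreme rank differences. A degenerate column (max = min) maps to all 0.
#'
#' @param ep `edge_profiles` in raw state.
#' @return `edge_profiles` with `state = "minmax"`.
#' @export
minmax_normalize <- function(ep) {
  stopifnot(inherits(ep, "edge_profiles"))
  if (ep$state != "raw")
    stop("minmax_normalize expects raw profiles", call. = FALSE)
  v <- ep$values
  storage.mode(v) <- "double"
  mins <- apply(v, 2, min)
  rngs <- apply(v, 2, max) - mins
  v <- sweep(v, 2, mins)
  nz <- rngs > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2, rngs[nz], "/")
  v[, !nz] <- 0
  ep$values <- v
  ep$state <- "minmax"
  ep
}

#' Keep the edge rows with the highest coefficient of variation
#'
#' Computes per edge row the coefficient of variation (sd / mean across
#' cells) of the normalized profile, after dropping rows with mean 0, and
#' keeps the `ceiling(top_fraction * n)` rows with the largest CV (at least
#' `min_keep`). Ties are broken by row order; kept rows retain their
#' original order.
#'
#' @param ep Normalized `edge_profiles`.
#' @param top_fraction Fraction of rows to keep. Default 0.01.
#' @param min_keep Floor on the number of rows kept. Default 1.
#' @return Filtered `edge_profiles` with a `cv` component.
#' @export
filter_top_cv <- function(ep, top_fraction = 0.01, min_keep = 1L) {
  stopifnot(inherits(ep, "edge_profiles"))
  if (ep$state != "minmax")
    stop("filter_top_cv expects min-max normalized profiles", call. = FALSE)
  means <- rowMeans(ep$values)
  nonzero <- means > 0
  if (!any(nonzero))
    stop("every edge profile has zero mean; nothing to filter", call. = FALSE)
  v <- ep$values[nonzero, , drop = FALSE]
  edges <- ep$edges[nonzero, , drop = FALSE]
  cv <- apply(v, 1, sd) / rowMeans(v)
  n_keep <- min(nrow(v), max(ceiling(top_fraction * nrow(v)), min_keep))
  keep_idx <- sort(order(-cv)[seq_len(n_keep)])   # order() is stable: ties by row
  structure(list(values = v[keep_idx, , drop = FALSE],
                 edges = edges[keep_idx, , drop = FALSE],
                 state = "minmax",
                 cv = cv[keep_idx]),
            class = "edge_profiles")
}

#' Write edge profiles as TSV
#'
#' Rows are labelled `"geneA|geneB"`; columns are cells.
#'
#' @param ep `edge_profiles`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_profiles <- function(ep, path) {
  df <- data.frame(edge = rownames(ep$values), ep$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
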