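#' Choose the start cluster from marker genes
#'
#' Scores every cluster by the mean z-score of a set of start-state marker
#' genes (each gene standardized across cells) and returns the top-scoring
#' cluster, mirroring how a root population is picked from prior knowledge
#' of, e.g., pluripotency markers.
#'
#' @param X Genes x cells matrix (log scale, pre-feature-selection, so
#'   markers need not be feature genes).
#' @param labels Named cluster vector over the same cells.
#' @param start_markers Character vector of marker gene identifiers.
#' @return List with `cluster` (the chosen label) and `scores` (per-cluster
#'   mean marker z-score).
#' @export
choose_start_cluster <- function(X, labels, start_markers) {
  labels <- labels[colnames(X)]
  if (anyNA(labels)) stop("labels must cover every cell", call. = FALSE)
  present <- intersect(start_markers, rownames(X))
  if (!length(present))
    stop("none of the start markers are present in the matrix", call. = FALSE)
  if (length(present) < length(start_markers))
    warning(sprintf("%d of %d start markers absent from the matrix",
                    length(start_markers) - length(present), length(start_markers)))
  Z <- X[present, , drop = FALSE]
  mu <- rowMeans(Z)
  sg <- apply(Z, 1, sd)
  sg[sg == 0] <- 1
  Z <- (Z - mu) / sg
  scores <- vapply(split(seq_along(labels), labels),
                   function(ix) mean(Z[, ix, drop = FALSE]), 0)
  list(cluster = names(scores)[which.max(scores)], scores = scores)
}

#' Assign per-cluster pseudotime from centroid distances
#'
#' Computes each cluster's centroid in the t-SNE plane, the Euclidean
#' distance `D_u` from every centroid to the start cluster's centroid, and a
#' pseudotime `T` in `[0, 1]` shared by all cells of a cluster.
#'
#' Two modes: `"normalized_distance"` (default) sets `T_u = D_u / max(D)`,
#' so stage times reflect how far along the map a cluster sits;
#' `"rank"` sets `T` from the ascending rank of `D_u`, rescaled to
#' `[0, 1]` as `(rank - 1) / (p - 1)`, so stages are equally spaced.
#'
#' @param coords Cells x 2 embedding coordinates (typically the t-SNE view).
#' @param labels Named cluster vector over the same cells.
#' @param start_cluster Label of the start cluster.
#' @param mode `"normalized_distance"` or `"rank"`.
#' @return Object of class `trajectory_model`: list with `start_cluster`,
#'   `centroids`, `D` (per-cluster distance), `cluster_T`, `cell_T` (named
#'   per cell), `labels`, `mode`; `paths` is filled by
#'   [derive_lineage_paths()].
#' @export
cluster_pseudotime <- function(coords, labels,
                               start_cluster,
                               mode = c("normalized_distance", "rank")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  labels <- labels[rownames(coords)]
  if (anyNA(labels)) stop("labels and coords must cover the same cells",
                          call. = FALSE)
  start_cluster <- as.character(start_cluster)
  cl <- sort(unique(as.character(labels)))
  if (!start_cluster %in% cl)
    stop("start cluster '", start_cluster, "' not found in the labels",
         call. = FALSE)
  centroids <- t(vapply(cl, function(u)
    colMeans(coords[labels == u, , drop = FALSE]), numeric(ncol(coords))))
  D <- sqrt(rowSums((centroids -
                     matrix(centroids[start_cluster, ], nrow(centroids),
                            ncol(centroids), byrow = TRUE))^2))
  p <- length(cl)
  if (p == 1) {
    warning("single cluster: pseudotime is 0 for every cell")
    Tc <- stats::setNames(0, cl)
  } else if (mode == "rank") {
    r <- rank(D, ties.method = "first")
    Tc <- (r - 1) / (p - 1)
  } else {
    mx <- max(D)
    if (mx == 0) {
      warning("all centroids coincide; pseudotime is 0 for every cluster")
      Tc <- stats::setNames(rep(0, p), cl)
    } else Tc <- D / mx
  }
  names(Tc) <- cl
  cell_T <- stats::setNames(Tc[as.character(labels)], rownames(coords))
  structure(list(start_cluster = start_cluster, centroids = centroids,
                 D = D, cluster_T = Tc, cell_T = cell_T,
                 labels = stats::setNames(as.character(labels), rownames(coords)),
                 mode = mode, paths = NULL),
            class = "trajectory_model")
}

#' Derive branch lineage paths from the centroid spanning tree
#'
#' Builds the complete graph on cluster centroids with Euclidean edge
#' weights, takes its minimum spanning tree, roots it at the start cluster,
#' and reports every root-to-leaf path as a lineage (ordered by the terminal
#' cluster's pseudotime). With a single cluster the lineage is that cluster
#' alone.
#'
#' @param model A `trajectory_model`.
#' @return The model with `paths` set: a list of cluster-label vectors, each
#'   starting at the start cluster.
#' @export
derive_lineage_paths <- function(model) {
  stopifnot(inherits(model, "trajectory_model"))
  cl <- rownames(model$centroids)
  if (length(cl) == 1) {
    model$paths <- list(cl)
    return(model)
  }
  dmat <- as.matrix(dist(model$centroids))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  deg <- igraph::degree(tree)
  leaves <- setdiff(names(deg)[deg == 1], model$start_cluster)
  if (!length(leaves)) leaves <- setdiff(cl, model$start_cluster)
  paths <- lapply(leaves, function(leaf) {
    sp <- igraph::shortest_paths(tree, from = model$start_cluster, to = leaf,
                                 weights = NA)$vpath[[1]]
    names(sp)
  })
  term_T <- vapply(paths, function(p) model$cluster_T[p[length(p)]], 0)
  model$paths <- paths[order(term_T)]
  model
}

#' Identify per-cluster marker genes
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene and cluster, with
#' Benjamini-Hochberg adjustment within each cluster. The fold change is
#' `log2((mean_in + 1) / (mean_out + 1))` on the supplied (log-scale)
#' matrix. Markers are genes with `log2FC > logfc_min` and adjusted
#' `p < alpha`; clusters of fewer than 3 cells are skipped with a warning.
#'
#' @param X Genes x cells matrix (log scale).
#' @param labels Named cluster vector.
#' @param logfc_min Fold-change cutoff. Default 1.
#' @param alpha Adjusted p-value cutoff. Default 0.05.
#' @return Data frame `cluster`, `gene`, `log2fc`, `p_value`, `p_adj`,
#'   sorted by cluster then decreasing fold change; zero rows when no gene
#'   passes.
#' @export
identify_marker_genes <- function(X, labels, logfc_min = 1, alpha = 0.05) {
  labels <- labels[colnames(X)]
  if (anyNA(labels)) stop("labels must cover every cell", call. = FALSE)
  out <- list()
  for (u in sort(unique(as.character(labels)))) {
    inside <- labels == u
    if (sum(inside) < 3) {
      warning("cluster ", u, " has fewer than 3 cells; skipped")
      next
    }
    mean_in <- rowMeans(X[, inside, drop = FALSE])
    mean_out <- rowMeans(X[, !inside, drop = FALSE])
    lfc <- log2((mean_in + 1) / (mean_out + 1))
    pv <- vapply(seq_len(nrow(X)), function(g)
      suppressWarnings(wilcox.test(X[g, inside], X[g, !inside],
                                   exact = FALSE)$p.value), 0)
    padj <- p.adjust(pv, method = "BH")
    hit <- which(lfc > logfc_min & padj < alpha)
    if (!length(hit)) next
    out[[u]] <- data.frame(cluster = u, gene = rownames(X)[hit],
                           log2fc = lfc[hit], p_value = pv[hit],
                           p_adj = padj[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cluster = character(), gene = character(),
                      log2fc = numeric(), p_value = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$cluster, -res$log2fc), , drop = FALSE]
  rownames(res) <- NULL
  res
}
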