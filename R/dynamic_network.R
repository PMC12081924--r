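#' Build the gene network at one pseudotime stage
#'
#' For every stored co-expression edge whose two endpoints are key genes,
#' the stage weight is the mean of the normalized rank-difference profile
#' over the cells assigned pseudotime `pt`; the once-stored oriented weights
#' are then mirrored into a symmetric matrix. Key-gene pairs that are not
#' co-expression edges are absent (isolated nodes are allowed, with a
#' warning for key genes touching no edge at all).
#'
#' @param ep Filtered, min-max normalized `edge_profiles`.
#' @param model A `trajectory_model` supplying each cell's pseudotime.
#' @param key_genes Character vector of genes to include as nodes.
#' @param pt One of the model's cluster pseudotimes.
#' @return Object of class `stage_network`: list with `pt`, `genes`,
#'   `weights` (symmetric matrix, zero diagonal), `edges` (data frame
#'   `gene_a`, `gene_b`, `weight`), `n_cells`, `threshold` (NULL until
#'   [threshold_network()]).
#' @export
stage_network <- function(ep, model, key_genes, pt) {
  stopifnot(inherits(ep, "edge_profiles"), inherits(model, "trajectory_model"))
  if (ep$state != "minmax")
    stop("stage_network expects min-max normalized profiles", call. = FALSE)
  cells <- names(model$cell_T)[abs(model$cell_T - pt) < 1e-9]
  cells <- intersect(cells, colnames(ep$values))
  if (!length(cells))
    stop("no cells carry pseudotime ", format(pt), call. = FALSE)
  sel <- ep$edges$gene_a %in% key_genes & ep$edges$gene_b %in% key_genes
  touched <- unique(c(ep$edges$gene_a, ep$edges$gene_b))
  orphan <- setdiff(key_genes, touched)
  if (length(orphan))
    warning("key gene(s) absent from every stored edge: ",
            paste(head(orphan, 5), collapse = ", "))
  W <- matrix(0, length(key_genes), length(key_genes),
              dimnames = list(key_genes, key_genes))
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (any(sel)) {
    w <- rowMeans(ep$values[sel, cells, drop = FALSE])
    edges <- data.frame(gene_a = ep$edges$gene_a[sel],
                        gene_b = ep$edges$gene_b[sel],
                        weight = unname(w), stringsAsFactors = FALSE)
    H <- W
    H[cbind(edges$gene_a, edges$gene_b)] <- edges$weight
    W <- H + t(H)                         # mirror the once-stored orientation
  }
  structure(list(pt = pt, genes = key_genes, weights = W, edges = edges,
                 n_cells = length(cells), threshold = NULL),
            class = "stage_network")
}

#' Discard weak stage-network edges
#'
#' Edges with weight strictly below `threshold` are removed (weight exactly
#' at the threshold survives).
#'
#' @param net A `stage_network`.
#' @param threshold Display threshold. Default 0.2.
#' @return The thresholded `stage_network`.
#' @export
threshold_network <- function(net, threshold = 0.2) {
  stopifnot(inherits(net, "stage_network"))
  net$weights[net$weights < threshold] <- 0
  net$edges <- net$edges[net$edges$weight >= threshold, , drop = FALSE]
  net$threshold <- threshold
  net
}

#' Node diversity: scaled Shannon entropy of incident edge weights
#'
#' For node `i` with degree `k_i` and incident weights `w_ij`, the weights
#' are normalized to `p_ij = w_ij / sum_l(w_il)` and the diversity is
#' `-sum(p_ij log p_ij) / log(k_i)`, so a node whose incident weights are
#' equal scores 1. Nodes of degree 0 or 1 score 0 (the `log k` scale
#' degenerates).
#'
#' @param net A (thresholded) `stage_network`.
#' @return Named numeric vector in `[0, 1]` per node.
#' @export
node_diversity <- function(net) {
  stopifnot(inherits(net, "stage_network"))
  W <- net$weights
  vapply(rownames(W), function(g) {
    w <- W[g, W[g, ] > 0]
    k <- length(w)
    if (k <= 1) return(0)
    p <- w / sum(w)
    -sum(p * log(p)) / log(k)
  }, 0)
}

#' Node clustering coefficient
#'
#' `CO(i) = 2 TR(i) / (k_i (k_i - 1))` with `TR(i)` the number of edges
#' among node `i`'s neighbours, counted on the unweighted edge skeleton.
#' Nodes of degree 0 or 1 score 0.
#'
#' @param net A (thresholded) `stage_network`.
#' @return Named numeric vector in `[0, 1]` per node.
#' @export
node_cluster_coefficient <- function(net) {
  stopifnot(inherits(net, "stage_network"))
  A <- net$weights > 0
  vapply(rownames(A), function(g) {
    neigh <- which(A[g, ])
    k <- length(neigh)
    if (k <= 1) return(0)
    tr <- sum(A[neigh, neigh]) / 2
    2 * tr / (k * (k - 1))
  }, 0)
}

#' Stage networks and topology summaries along a lineage path
#'
#' Builds one (thresholded) stage network per cluster on the path, in
#' pseudotime order, and summarises each stage by the mean node diversity
#' and mean clustering coefficient — the quantities whose rise and fall
#' along a lineage mark the most active differentiation stages.
#'
#' @param ep Filtered, normalized `edge_profiles`.
#' @param model A `trajectory_model` with `paths` set.
#' @param key_genes Nodes of the stage networks.
#' @param path A cluster-label vector (one entry of `model$paths`).
#' @param threshold Edge display threshold. Default 0.2.
#' @return List with `networks` (one `stage_network` per stage) and
#'   `summary` (data frame `cluster`, `T`, `n_cells`, `mean_diversity`,
#'   `mean_cluster_coefficient`).
#' @export
dynamics_along_path <- function(ep, model, key_genes, path, threshold = 0.2) {
  path <- path[order(model$cluster_T[path])]
  nets <- lapply(path, function(u) {
    net <- stage_network(ep, model, key_genes, model$cluster_T[[u]])
    threshold_network(net, threshold)
  })
  names(nets) <- path
  summary <- data.frame(
    cluster = path,
    T = unname(model$cluster_T[path]),
    n_cells = vapply(nets, `[[`, 0L, "n_cells"),
    mean_diversity = vapply(nets, function(n) mean(node_diversity(n)), 0),
    mean_cluster_coefficient =
      vapply(nets, function(n) mean(node_cluster_coefficient(n)), 0),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(networks = nets, summary = summary)
}
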