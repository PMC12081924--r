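#' Embed cells with PCA, t-SNE and UMAP
#'
#' Produces the three low-dimensional views of the edge-profile matrix
#' (cells as samples, edge profiles as features) that the kernel-fusion step
#' consumes. PCA keeps up to 30 components; t-SNE and UMAP are 2-dimensional
#' and seeded, so repeated calls with the same seed give identical
#' coordinates.
#'
#' @param ep Filtered, normalized `edge_profiles` (or a plain cells x
#'   features matrix).
#' @param seed Integer seed for t-SNE and UMAP.
#' @param pca_dims Maximum PCA dimensionality. Default 30.
#' @param perplexity t-SNE perplexity; clipped to `(n - 1) / 3`. Default 30.
#' @param umap_neighbors UMAP neighbourhood size; clipped to `n - 1`.
#'   Default 15.
#' @return Object of class `embedding_set`: list of coordinate matrices
#'   `pca`, `tsne`, `umap` (same cell order) plus `seed`.
#' @export
embed_views <- function(ep, seed = 1L, pca_dims = 30,
                        perplexity = 30, umap_neighbors = 15) {
  X <- if (inherits(ep, "edge_profiles")) t(ep$values) else as.matrix(ep)
  n <- nrow(X)
  if (n < 2) stop("embed_views needs at least 2 cells", call. = FALSE)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  pca <- pr$x[, seq_len(min(pca_dims, ncol(pr$x))), drop = FALSE]

  perp <- min(perplexity, floor((n - 1) / 3))
  if (perp < 1)
    stop("too few cells for t-SNE (need n >= 4)", call. = FALSE)
  set.seed(as.integer(seed))
  ts <- Rtsne::Rtsne(X, dims = 2, perplexity = perp, check_duplicates = FALSE,
                     pca = TRUE, verbose = FALSE)$Y
  rownames(ts) <- rownames(X)

  set.seed(as.integer(seed))
  um <- uwot::umap(X, n_components = 2,
                   n_neighbors = min(umap_neighbors, n - 1),
                   n_threads = 1, n_sgd_threads = 1)
  rownames(um) <- rownames(X)

  structure(list(pca = pca, tsne = ts, umap = um, seed = as.integer(seed)),
            class = "embedding_set")
}

#' Local-scaling similarity kernels for one embedding
#'
#' From the pairwise Euclidean distances of one low-dimensional view, builds
#' the locally scaled Gaussian similarity `W`, its row-normalized full kernel
#' `P` (off-diagonal mass 1/2, diagonal exactly 1/2, rows summing to 1) and
#' the sparse k-nearest-neighbour kernel `S` (rows summing to 1/2 over the
#' neighbourhood, zero elsewhere).
#'
#' The local scale for a pair is the mean of three terms: each cell's average
#' distance to its `k` nearest neighbours and the pair distance itself;
#' `W_ij = exp(-d_ij^2 / (mu * eps_ij))`. Coincident points that would make
#' the scale zero are floored at 1e-12.
#'
#' @param coords Cells x dims coordinate matrix.
#' @param k Neighbourhood size; must be smaller than the number of cells.
#' @param mu Bandwidth multiplier. Default 0.5.
#' @return List with matrices `W`, `P`, `S` (cells x cells).
#' @export
local_scaling_kernel <- function(coords, k = 30, mu = 0.5) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("'k' must be smaller than the number of cells", call. = FALSE)
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  rho <- as.matrix(dist(coords))
  nn <- t(apply(rho, 1, function(d) order(d)[2:(k + 1)]))   # self at position 1
  rho_bar <- vapply(seq_len(n), function(i) mean(rho[i, nn[i, ]]), 0)
  eps <- (outer(rho_bar, rho_bar, "+") + rho) / 3
  eps <- pmax(eps, 1e-12)
  W <- exp(-rho^2 / (mu * eps))
  P <- kernel_row_normalize(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    wi <- W[i, nn[i, ]]
    S[i, nn[i, ]] <- wi / (2 * sum(wi))
  }
  list(W = W, P = P, S = S)
}

# Row normalization to the full-kernel structure: off-diagonal entries carry
# half of each row's mass, the diagonal exactly 1/2.
kernel_row_normalize <- function(W) {
  n <- nrow(W)
  off <- W
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- 1                       # isolated row: keep zeros off-diagonal
  P <- off / (2 * rs)
  diag(P) <- 0.5
  P
}

#' Fuse the per-view kernels by iterative cross-diffusion
#'
#' Starting from the full kernels `P^(v)`, each sweep updates every view as
#' `S^(v) %*% mean(other views' P) %*% t(S^(v))` (all updates computed from
#' the previous iterate), then re-symmetrizes each view and renormalizes its
#' rows back to the half-diagonal structure so the spectral step stays
#' well-posed. Sweeps stop at `iters_max`, or before applying a sweep whose
#' maximum entry change is below `tol` — so with `tol = Inf` the fused
#' result is the mean of the initial kernels. The fused affinity is the mean
#' of the converged views, symmetrized.
#'
#' @param views List of at least two `list(P, S)` pairs over the same cells
#'   (e.g. from [local_scaling_kernel()] on each embedding).
#' @param iters_max Maximum sweeps. Default 20.
#' @param tol Convergence tolerance on the max entry change. Default 1e-6.
#' @return Object of class `fused_affinity`: list with `E` (fused symmetric
#'   matrix), `P` (final per-view kernels), `iterations`, and `diagnostics`
#'   (per sweep: max change, max row-sum deviation and max diagonal
#'   deviation after renormalization).
#' @export
fuse_views <- function(views, iters_max = 20, tol = 1e-6) {
  m <- length(views)
  if (m < 2)
    stop("kernel fusion needs at least two views; with a single view run ",
         "spectral clustering on its P directly", call. = FALSE)
  dims <- vapply(views, function(v) nrow(v$P), 0L)
  if (length(unique(dims)) != 1)
    stop("all views must cover the same cell set", call. = FALSE)
  Ps <- lapply(views, `[[`, "P")
  Ss <- lapply(views, `[[`, "S")
  diagnostics <- data.frame(iteration = integer(), delta = numeric(),
                            max_rowsum_dev = numeric(), max_diag_dev = numeric())
  iterations <- 0L
  for (it in seq_len(iters_max)) {
    newPs <- vector("list", m)
    for (v in seq_len(m)) {
      cross <- Reduce(`+`, Ps[-v]) / (m - 1)
      Pv <- Ss[[v]] %*% cross %*% t(Ss[[v]])
      Pv <- (Pv + t(Pv)) / 2
      newPs[[v]] <- kernel_row_normalize(Pv)
    }
    delta <- max(vapply(seq_len(m),
                        function(v) max(abs(newPs[[v]] - Ps[[v]])), 0))
    if (delta < tol) break                 # discard the sub-tolerance sweep
    Ps <- newPs
    iterations <- it
    diagnostics <- rbind(diagnostics, data.frame(
      iteration = it, delta = delta,
      max_rowsum_dev = max(vapply(Ps, function(P) max(abs(rowSums(P) - 1)), 0)),
      max_diag_dev = max(vapply(Ps, function(P) max(abs(diag(P) - 0.5)), 0))))
  }
  E <- Reduce(`+`, Ps) / m
  E <- (E + t(E)) / 2
  structure(list(E = E, P = Ps, iterations = iterations,
                 diagnostics = diagnostics),
            class = "fused_affinity")
}

#' Choose the cluster count from the Laplacian eigengap
#'
#' Forms the unnormalized Laplacian `L = D - E`, sorts its eigenvalues
#' ascending and examines the gaps `lambda[i+1] - lambda[i]` for `i` in
#' `2..i_max` (so a single cluster is never auto-selected). The default rule
#' returns the index of the largest gap (ties toward smaller `i`) — the
#' standard eigengap heuristic, which recovers the block count of planted
#' block affinities. `rule = "top2_smaller_value"` instead takes the two
#' largest gaps and returns the index of the smaller-valued one.
#'
#' @param E Symmetric non-negative affinity matrix.
#' @param i_max Largest cluster count considered. Default 15.
#' @param rule `"max_gap"` (default) or `"top2_smaller_value"`.
#' @param n_override If supplied, returned as `p` with the rule skipped
#'   (mirrors choosing the cluster count from prior knowledge).
#' @return List with `p`, `eigenvalues` (ascending), `gaps` (data frame `i`,
#'   `gap`), `rule`.
#' @export
eigengap_cluster_count <- function(E, i_max = 15,
                                   rule = c("max_gap", "top2_smaller_value"),
                                   n_override = NULL) {
  rule <- match.arg(rule)
  if (!is.null(n_override))
    return(list(p = as.integer(n_override), eigenvalues = NULL, gaps = NULL,
                rule = "user"))
  if (!isSymmetric(unname(E), tol = 1e-8))
    stop("affinity matrix must be symmetric", call. = FALSE)
  E <- (E + t(E)) / 2
  L <- diag(rowSums(E)) - E
  lam <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  n <- length(lam)
  idx <- 2:min(i_max, n - 1)
  gaps <- lam[idx + 1] - lam[idx]
  ord <- order(-gaps, idx)                 # decreasing gap, ties toward small i
  p <- switch(rule,
              max_gap = idx[ord[1]],
              top2_smaller_value = {
                top2 <- ord[1:2]
                idx[top2[which.min(gaps[top2])]]
              })
  list(p = as.integer(p), eigenvalues = lam,
       gaps = data.frame(i = idx, gap = gaps), rule = rule)
}

#' Spectral clustering of the fused affinity
#'
#' Embeds cells in the eigenvectors of the unnormalized Laplacian belonging
#' to the `p` smallest eigenvalues, row-normalizes the spectral coordinates
#' to unit length, and runs seeded k-means with 50 restarts. Cluster labels
#' are relabelled in order of decreasing size (cluster 1 is the largest).
#'
#' @param E Symmetric affinity matrix with cell names.
#' @param p Number of clusters.
#' @param seed Seed for k-means.
#' @return Named integer vector of cluster labels in `1..p`.
#' @export
spectral_cluster <- function(E, p, seed = 1L) {
  n <- nrow(E)
  if (p < 1) stop("'p' must be >= 1", call. = FALSE)
  if (p > n) stop("'p' exceeds the number of cells", call. = FALSE)
  ids <- rownames(E)
  if (is.null(ids)) ids <- paste0("cell", seq_len(n))
  if (p == 1) return(stats::setNames(rep(1L, n), ids))
  E <- (E + t(E)) / 2
  L <- diag(rowSums(E)) - E
  dec <- eigen(L, symmetric = TRUE)
  V <- dec$vectors[, n:1, drop = FALSE][, seq_len(p), drop = FALSE]
  len <- sqrt(rowSums(V^2))
  len[len == 0] <- 1
  V <- V / len
  set.seed(as.integer(seed))
  km <- kmeans(V, centers = p, nstart = 50, iter.max = 100)
  sizes <- tabulate(km$cluster, p)
  relabel <- integer(p)
  relabel[order(-sizes, seq_len(p))] <- seq_len(p)
  stats::setNames(relabel[km$cluster], ids)
}
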