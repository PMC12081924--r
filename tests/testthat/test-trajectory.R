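test_that("the start cluster is the one with the highest marker score", {
  X <- rand_expr(5, 9, seed = 1)
  lab <- stats::setNames(rep(1:3, each = 3), colnames(X))
  # single cluster: trivially that cluster
  one <- stats::setNames(rep(1L, 9), colnames(X))
  expect_identical(choose_start_cluster(X, one, "g01")$cluster, "1")
  # marker expressed exclusively in cluster 2
  X["g02", ] <- 0
  X["g02", lab == 2] <- 50
  expect_identical(choose_start_cluster(X, lab, "g02")$cluster, "2")
  expect_error(choose_start_cluster(X, lab, "absent"), "none of the start markers")
})

test_that("root-module markers pick the earliest cluster on synthetic truth", {
  sim <- simulate_branching(n_genes = 200, n_cells = 200, n_branches = 1,
                            seed = 5)
  mods <- sim$truth$module_assignment
  ci <- sim$truth$cell_info
  lg <- log_transform(sim$matrix)
  # clusters = time quartiles (labels independent of the marker scoring)
  lab <- stats::setNames(as.integer(cut(ci$true_time, 4)), ci$cell_id)
  down <- names(mods)[mods == "ramp_down"][1:10]
  pick <- choose_start_cluster(lg, lab, down)
  mean_t <- tapply(ci$true_time, lab, mean)
  expect_identical(pick$cluster, names(which.min(mean_t)))
})

test_that("cluster pseudotime is centroid distance to the start, scaled to [0,1]", {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0))[rep(1:3, each = 4), ]
  rownames(coords) <- sprintf("c%02d", 1:12)
  lab <- stats::setNames(rep(c("A", "B", "C"), each = 4), rownames(coords))
  m <- cluster_pseudotime(coords, lab, "A", mode = "normalized_distance")
  expect_equal(unname(m$cluster_T), c(0, 0.5, 1))
  expect_equal(unname(m$cell_T[1]), 0)
  r <- cluster_pseudotime(coords, lab, "A", mode = "rank")
  expect_equal(unname(r$cluster_T), c(0, 0.5, 1))
  # rank-mode ordering equals the brute-force sort of centroid distances
  set.seed(7)
  coords2 <- matrix(rnorm(80), 40, 2)
  rownames(coords2) <- sprintf("c%02d", 1:40)
  lab2 <- stats::setNames(rep(1:4, each = 10), rownames(coords2))
  r2 <- cluster_pseudotime(coords2, lab2, "2", mode = "rank")
  cen <- t(vapply(split(seq_len(40), lab2),
                  function(ix) colMeans(coords2[ix, , drop = FALSE]),
                  numeric(2)))
  D <- sqrt(rowSums((cen - rep(cen["2", ], each = 4))^2))
  expect_equal(order(r2$cluster_T), order(D))
  expect_true(all(r2$cluster_T >= 0 & r2$cluster_T <= 1))
  expect_equal(unname(r2$cluster_T["2"]), 0)
  expect_warning(cluster_pseudotime(coords[1:4, ], lab[1:4], "A"), "single cluster")
})

test_that("lineage paths follow the centroid spanning tree from the start", {
  collinear <- rbind(A = c(0, 0), B = c(1, 0), C = c(2, 0))
  mk <- function(cen, start) {
    n <- nrow(cen)
    structure(list(start_cluster = start, centroids = cen,
                   cluster_T = stats::setNames(seq(0, 1, length.out = n),
                                               rownames(cen)),
                   labels = NULL, cell_T = NULL, mode = "normalized_distance",
                   D = NULL, paths = NULL),
              class = "trajectory_model")
  }
  m <- derive_lineage_paths(mk(collinear, "A"))
  expect_equal(m$paths, list(c("A", "B", "C")))
  # Y layout: root, junction, two leaves
  y <- rbind(root = c(0, 0), junc = c(1, 0), leaf1 = c(2, 1), leaf2 = c(2, -1))
  my <- derive_lineage_paths(mk(y, "root"))
  expect_length(my$paths, 2)
  expect_true(all(vapply(my$paths, function(p) all(p[1:2] == c("root", "junc")),
                         TRUE)))
  expect_setequal(vapply(my$paths, function(p) p[3], ""), c("leaf1", "leaf2"))
  # paths jointly cover every cluster, each at most once per path
  expect_setequal(unique(unlist(my$paths)), rownames(y))
  expect_true(all(vapply(my$paths, anyDuplicated, 0L) == 0))
  single <- derive_lineage_paths(mk(rbind(A = c(0, 0)), "A"))
  expect_equal(single$paths, list("A"))
})

test_that("marker tests combine a fold-change cut with BH-adjusted Wilcoxon", {
  set.seed(9)
  n <- 40
  X <- matrix(rpois(20 * n, 3), 20, n,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:n)))
  lab <- stats::setNames(rep(c("A", "B"), each = n / 2), colnames(X))
  X["g01", ] <- 1; X["g01", lab == "A"] <- 8    # log2(9/2) > 1, huge separation
  X["g02", ] <- 5                               # identical everywhere
  res <- identify_marker_genes(log2(X + 1), lab, logfc_min = 0.5)
  hitA <- res[res$cluster == "A", ]
  expect_true("g01" %in% hitA$gene)
  expect_false("g02" %in% res$gene)
  # BH oracle: adjusted p equals p.adjust of the per-gene Wilcoxon p-values
  lg <- log2(X + 1)
  pv <- vapply(rownames(lg), function(g)
    suppressWarnings(wilcox.test(lg[g, lab == "A"], lg[g, lab == "B"],
                                 exact = FALSE)$p.value), 0)
  padj <- p.adjust(pv, "BH")
  expect_equal(hitA$p_adj[hitA$gene == "g01"], unname(padj["g01"]),
               tolerance = 1e-12)
  # impossible threshold: empty table with the documented columns
  none <- identify_marker_genes(log2(X + 1), lab, logfc_min = 100)
  expect_equal(nrow(none), 0)
  expect_true(all(c("cluster", "gene", "log2fc", "p_adj") %in% names(none)))
  # tiny cluster is skipped with a warning
  lab2 <- lab; lab2[1:2] <- "C"
  expect_warning(identify_marker_genes(log2(X + 1), lab2), "fewer than 3")
})
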