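test_that("embeddings are deterministic under a fixed seed", {
  set.seed(1)
  v <- matrix(runif(40 * 50), 40, 50)    # 40 edges x 50 cells
  colnames(v) <- sprintf("c%02d", 1:50)
  ep <- structure(list(values = v, state = "minmax"), class = "edge_profiles")
  a <- embed_views(ep, seed = 4)
  b <- embed_views(ep, seed = 4)
  expect_identical(a$tsne, b$tsne)
  expect_identical(a$umap, b$umap)
  expect_identical(a$pca, b$pca)
  expect_true(all(vapply(a[c("pca", "tsne", "umap")],
                         function(x) identical(rownames(x), colnames(v)), TRUE)))
})

test_that("PCA view respects duplicate cells and rank-1 structure", {
  v <- matrix(runif(20 * 12), 20, 12)
  v[, 2] <- v[, 1]                        # duplicate cells
  colnames(v) <- sprintf("c%02d", 1:12)
  ep <- structure(list(values = v, state = "minmax"), class = "edge_profiles")
  emb <- embed_views(ep, seed = 1)
  expect_equal(emb$pca[1, ], emb$pca[2, ])
  r1 <- outer(runif(20), runif(12))       # rank-1 matrix
  colnames(r1) <- sprintf("c%02d", 1:12)
  pr <- prcomp(t(r1))
  expect_equal(sum(pr$sdev > 1e-8), 1)
})

test_that("local-scaling kernels match a brute-force evaluation", {
  set.seed(2)
  coords <- matrix(rnorm(10), 5, 2)
  rownames(coords) <- paste0("c", 1:5)
  got <- local_scaling_kernel(coords, k = 2, mu = 0.6)
  want <- oracle_kernel(coords, k = 2, mu = 0.6)
  expect_equal(unname(got$W), want$W, tolerance = 1e-10)
  expect_equal(unname(got$P), want$P, tolerance = 1e-10)
  expect_equal(unname(got$S), want$S, tolerance = 1e-10)
  # structural identities of the full and sparse kernels
  expect_equal(unname(rowSums(got$P)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(diag(got$P)), rep(0.5, 5))
  expect_equal(unname(rowSums(got$S)), rep(0.5, 5), tolerance = 1e-12)
  expect_error(local_scaling_kernel(coords, k = 5), "smaller")
})

test_that("fusion preserves row structure, symmetry, and block diagonals", {
  set.seed(3)
  coords <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 30), 10, 2))
  rownames(coords) <- paste0("c", 1:20)
  kern <- local_scaling_kernel(coords, k = 3, mu = 0.5)
  views <- list(kern, kern, kern)
  fus <- fuse_views(views, iters_max = 10, tol = 0)
  expect_true(isSymmetric(fus$E, tol = 1e-12))
  expect_true(all(fus$diagnostics$max_rowsum_dev < 1e-10))
  expect_true(all(fus$diagnostics$max_diag_dev < 1e-10))
  # two planted blocks: cross-block mass stays negligible
  cross <- fus$E[1:10, 11:20]
  within <- fus$E[1:10, 1:10]
  expect_lt(max(cross), 1e-6)
  expect_gt(mean(within[upper.tri(within)]), 1e-4)
  expect_error(fuse_views(views[1]), "at least two")
})

test_that("a dense one-iteration update matches the matrix-product oracle", {
  set.seed(4)
  coords <- matrix(rnorm(16), 8, 2)
  rownames(coords) <- paste0("c", 1:8)
  k1 <- local_scaling_kernel(coords, k = 3, mu = 0.5)
  k2 <- local_scaling_kernel(coords * 2, k = 3, mu = 0.5)
  dense <- function(kk) list(P = kk$P, S = kk$P)   # S = P: no sparsification
  fus <- fuse_views(list(dense(k1), dense(k2)), iters_max = 1, tol = 0)
  # brute-force: P_new^(v) = P^(v) %*% P^(other) %*% t(P^(v)), then
  # symmetrized and renormalized to the half-diagonal row structure
  renorm <- function(M) {
    M <- (M + t(M)) / 2
    off <- M; diag(off) <- 0
    P <- off / (2 * rowSums(off)); diag(P) <- 0.5
    P
  }
  w1 <- renorm(k1$P %*% k2$P %*% t(k1$P))
  w2 <- renorm(k2$P %*% k1$P %*% t(k2$P))
  expect_equal(unname(fus$P[[1]]), unname(w1), tolerance = 1e-12)
  expect_equal(unname(fus$P[[2]]), unname(w2), tolerance = 1e-12)
})

test_that("an infinite tolerance returns the mean of the initial kernels", {
  set.seed(5)
  coords <- matrix(rnorm(24), 12, 2)
  rownames(coords) <- paste0("c", 1:12)
  ks <- lapply(c(1, 2, 3), function(s) local_scaling_kernel(coords * s, k = 3))
  fus <- fuse_views(ks, iters_max = 20, tol = Inf)
  expect_equal(fus$iterations, 0L)
  E0 <- (ks[[1]]$P + ks[[2]]$P + ks[[3]]$P) / 3
  expect_equal(fus$E, (E0 + t(E0)) / 2, tolerance = 1e-12)
})

test_that("fusion is invariant under simultaneous cell permutation", {
  set.seed(6)
  coords <- matrix(rnorm(30), 15, 2)
  rownames(coords) <- paste0("c", 1:15)
  ks <- lapply(c(1, 1.5, 2), function(s) local_scaling_kernel(coords * s, k = 4))
  fusA <- fuse_views(ks, iters_max = 5, tol = 0)
  perm <- sample(15)
  ksP <- lapply(ks, function(kk) list(P = kk$P[perm, perm], S = kk$S[perm, perm]))
  fusB <- fuse_views(ksP, iters_max = 5, tol = 0)
  expect_equal(fusB$E, fusA$E[perm, perm], tolerance = 1e-12)
})

test_that("the eigengap rule recovers planted block counts", {
  E3 <- planted_affinity(3, across = 0, noise = 0)   # exactly block diagonal
  L <- diag(rowSums(E3)) - E3
  lam <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(sum(abs(lam) < 1e-8), 3)      # eigenvalue 0 has multiplicity 3
  eg3 <- eigengap_cluster_count(E3)
  expect_equal(eg3$p, 3L)
  expect_equal(eg3$gaps$i[which.max(eg3$gaps$gap)], 3)
  for (nb in c(3, 4)) {                      # noisy planted blocks, fixed seed
    eg <- eigengap_cluster_count(planted_affinity(nb, noise = 0.02, seed = 17))
    expect_equal(eg$p, nb)
  }
  # user override skips the rule entirely
  egu <- eigengap_cluster_count(planted_affinity(3), n_override = 8)
  expect_equal(egu$p, 8L)
  expect_identical(egu$rule, "user")
  expect_error(eigengap_cluster_count(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("spectral clustering splits well-separated blocks exactly", {
  E <- planted_affinity(2, per = 15, seed = 8)
  lab <- spectral_cluster(E, 2, seed = 1)
  truth <- rep(1:2, each = 15)
  expect_equal(unname(clustering_agreement(lab, truth)["ari"]), 1)
  expect_equal(unique(unname(spectral_cluster(E, 1))), 1L)
  expect_error(spectral_cluster(E, 31), "exceeds")
  # permutation equivariance
  perm <- sample(30)
  labP <- spectral_cluster(E[perm, perm], 2, seed = 1)
  expect_equal(unname(clustering_agreement(labP, lab[perm])["ari"]), 1)
})
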