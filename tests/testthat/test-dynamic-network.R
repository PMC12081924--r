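# small hand-built profile set + trajectory for stage-network tests:
# 3 key genes, 5 cells in two stages (pt 0 for c1-c3, pt 1 for c4-c5)
make_stage_fixture <- function(values = NULL) {
  v <- values %||% rbind(
    "gA|gB" = c(0.6, 0.6, 0.6, 0.9, 0.7),
    "gA|gC" = c(0.1, 0.3, 0.2, 0.8, 0.6),
    "gB|gC" = c(0.4, 0.5, 0.6, 0.3, 0.5))
  colnames(v) <- paste0("c", 1:5)
  ep <- structure(list(values = v,
                       edges = data.frame(gene_a = c("gA", "gA", "gB"),
                                          gene_b = c("gB", "gC", "gC")),
                       state = "minmax"), class = "edge_profiles")
  cell_T <- stats::setNames(c(0, 0, 0, 1, 1), colnames(v))
  model <- structure(list(start_cluster = "1",
                          centroids = rbind("1" = c(0, 0), "2" = c(1, 0)),
                          cluster_T = c("1" = 0, "2" = 1),
                          cell_T = cell_T,
                          labels = stats::setNames(c(1, 1, 1, 2, 2), names(cell_T)),
                          mode = "normalized_distance", D = c(0, 1),
                          paths = list(c("1", "2"))),
                     class = "trajectory_model")
  list(ep = ep, model = model)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("stage weights are group means of normalized profiles, mirrored", {
  fx <- make_stage_fixture()
  net0 <- stage_network(fx$ep, fx$model, c("gA", "gB", "gC"), pt = 0)
  # an edge constant at 0.6 across the stage's cells has weight 0.6
  expect_equal(net0$weights["gA", "gB"], 0.6)
  expect_equal(net0$weights["gB", "gA"], 0.6)        # mirrored
  expect_identical(net0$weights, t(net0$weights))    # machine equality
  expect_equal(diag(net0$weights), c(gA = 0, gB = 0, gC = 0))
  # brute-force group-mean oracle over all edges and both stages
  for (pt in c(0, 1)) {
    net <- stage_network(fx$ep, fx$model, c("gA", "gB", "gC"), pt = pt)
    cells <- names(fx$model$cell_T)[fx$model$cell_T == pt]
    for (k in 1:3) {
      a <- fx$ep$edges$gene_a[k]; b <- fx$ep$edges$gene_b[k]
      expect_equal(net$weights[a, b], mean(fx$ep$values[k, cells]))
    }
  }
  # a stage holding a single cell reproduces that cell's profile values
  fx1 <- make_stage_fixture()
  fx1$model$cell_T <- stats::setNames(c(0, 0, 0, 0, 1), paste0("c", 1:5))
  net1 <- stage_network(fx1$ep, fx1$model, c("gA", "gB", "gC"), pt = 1)
  expect_equal(net1$weights["gA", "gC"], fx1$ep$values["gA|gC", "c5"])
  expect_error(stage_network(fx$ep, fx$model, c("gA", "gB"), pt = 0.37),
               "no cells")
  expect_warning(stage_network(fx$ep, fx$model, c("gA", "gB", "gC", "gZ"), 0),
                 "gZ")
})

test_that("thresholding discards strictly sub-threshold edges only", {
  fx <- make_stage_fixture(rbind("gA|gB" = rep(0.19, 5),
                                 "gA|gC" = rep(0.2, 5),
                                 "gB|gC" = rep(0.5, 5)))
  net <- stage_network(fx$ep, fx$model, c("gA", "gB", "gC"), pt = 0)
  thr <- threshold_network(net, 0.2)
  expect_equal(thr$weights["gA", "gB"], 0)      # 0.19 removed
  expect_equal(thr$weights["gA", "gC"], 0.2)    # exactly 0.2 survives
  expect_equal(thr$weights["gB", "gC"], 0.5)
  # threshold 0 is the identity
  expect_identical(threshold_network(net, 0)$weights, net$weights)
  # random instance vs elementwise comparison oracle
  set.seed(11)
  genes <- paste0("g", 1:6)
  pairs <- t(combn(genes, 2))
  v <- matrix(runif(15 * 5), 15, 5, dimnames = list(
    paste(pairs[, 1], pairs[, 2], sep = "|"), paste0("c", 1:5)))
  fx6 <- make_stage_fixture()
  ep6 <- structure(list(values = v,
                        edges = data.frame(gene_a = pairs[, 1],
                                           gene_b = pairs[, 2]),
                        state = "minmax"), class = "edge_profiles")
  net6 <- stage_network(ep6, fx6$model, genes, pt = 0)
  thr6 <- threshold_network(net6, 0.4)
  want <- net6$weights; want[want < 0.4] <- 0
  expect_identical(thr6$weights, want)
})

test_that("node diversity is the scaled entropy of incident weights", {
  w <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  w["g1", "g2"] <- w["g2", "g1"] <- 0.6
  w["g1", "g3"] <- w["g3", "g1"] <- 0.2
  w["g1", "g4"] <- w["g4", "g1"] <- 0.2
  net <- structure(list(pt = 0, genes = rownames(w), weights = w,
                        edges = NULL, threshold = 0.1),
                   class = "stage_network")
  div <- node_diversity(net)
  # direct evaluation: p = (.6,.2,.2)/1, SE = -sum p log p, scaled by log 3
  p <- c(0.6, 0.2, 0.2)
  expect_equal(unname(div["g1"]), -sum(p * log(p)) / log(3), tolerance = 1e-12)
  expect_equal(unname(div["g2"]), 0)   # degree 1: degenerate rule
  # equal weights give diversity exactly 1
  weq <- w; weq[weq > 0] <- 0.3
  neteq <- net; neteq$weights <- weq
  expect_equal(unname(node_diversity(neteq)["g1"]), 1)
  expect_true(all(div >= 0 & div <= 1))
})

test_that("clustering coefficients count closed neighbour triangles", {
  tri <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  tri["g1", "g2"] <- tri["g2", "g1"] <- 0.5
  tri["g2", "g3"] <- tri["g3", "g2"] <- 0.5
  tri["g1", "g3"] <- tri["g3", "g1"] <- 0.5
  tri["g1", "g4"] <- tri["g4", "g1"] <- 0.5     # pendant
  net <- structure(list(pt = 0, genes = rownames(tri), weights = tri,
                        edges = NULL, threshold = 0), class = "stage_network")
  co <- node_cluster_coefficient(net)
  expect_equal(unname(co["g2"]), 1)     # in a closed triangle
  expect_equal(unname(co["g4"]), 0)     # leaf
  expect_equal(unname(co["g1"]), 2 * 1 / (3 * 2))  # one triangle among 3 neighbours
  # star centre has no closed triangles
  star <- matrix(0, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  star[1, 2:5] <- star[2:5, 1] <- 0.4
  nets <- net; nets$weights <- star; nets$genes <- rownames(star)
  expect_equal(unname(node_cluster_coefficient(nets)["g1"]), 0)
  # brute-force triple loop on a random 6-node graph
  set.seed(13)
  A <- matrix(0, 6, 6); A[upper.tri(A)] <- rbinom(15, 1, 0.5) * runif(15)
  A <- A + t(A); dimnames(A) <- list(paste0("g", 1:6), paste0("g", 1:6))
  netr <- net; netr$weights <- A; netr$genes <- rownames(A)
  got <- node_cluster_coefficient(netr)
  Ab <- A > 0
  for (i in 1:6) {
    nb <- which(Ab[i, ]); k <- length(nb); tr <- 0
    if (k >= 2) for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && Ab[nb[a], nb[b]]) tr <- tr + 1
    expect_equal(unname(got[i]), if (k <= 1) 0 else 2 * tr / (k * (k - 1)))
  }
})

test_that("dynamics along a path order stages by pseudotime and track change", {
  fx <- make_stage_fixture()
  dyn <- dynamics_along_path(fx$ep, fx$model, c("gA", "gB", "gC"),
                             fx$model$paths[[1]], threshold = 0)
  expect_length(dyn$networks, 2)
  expect_equal(dyn$summary$T, c(0, 1))
  expect_true(all(dyn$summary$mean_diversity >= 0 &
                  dyn$summary$mean_diversity <= 1))
  # single-stage path
  one <- dynamics_along_path(fx$ep, fx$model, c("gA", "gB", "gC"), "1",
                             threshold = 0)
  expect_length(one$networks, 1)
  # identical cell populations at two stages give identical networks
  fx2 <- make_stage_fixture(rbind("gA|gB" = c(0.4, 0.4, 0.4, 0.4, 0.4),
                                  "gA|gC" = c(0.7, 0.2, 0.7, 0.2, 0.45),
                                  "gB|gC" = c(0.3, 0.9, 0.3, 0.9, 0.6)))
  fx2$model$cell_T <- stats::setNames(c(0, 0, 1, 1, 2), paste0("c", 1:5))
  netA <- stage_network(fx2$ep, fx2$model, c("gA", "gB", "gC"), 0)
  netB <- stage_network(fx2$ep, fx2$model, c("gA", "gB", "gC"), 1)
  expect_equal(netA$weights, netB$weights)
  # a module switching on mid-trajectory strengthens its internal edges
  ramp <- make_stage_fixture(rbind("gA|gB" = c(0.1, 0.1, 0.1, 0.8, 0.8),
                                   "gA|gC" = c(0.1, 0.2, 0.1, 0.7, 0.9),
                                   "gB|gC" = c(0.5, 0.5, 0.5, 0.5, 0.5)))
  dr <- dynamics_along_path(ramp$ep, ramp$model, c("gA", "gB", "gC"),
                            c("1", "2"), threshold = 0)
  w1 <- dr$networks[[1]]$weights; w2 <- dr$networks[[2]]$weights
  expect_gt(w2["gA", "gB"], w1["gA", "gB"])
  expect_gt(w2["gA", "gC"], w1["gA", "gC"])
})

test_that("stage networks are invariant to key-gene order and cell permutation", {
  fx <- make_stage_fixture()
  a <- stage_network(fx$ep, fx$model, c("gA", "gB", "gC"), 0)
  b <- stage_network(fx$ep, fx$model, c("gC", "gA", "gB"), 0)
  expect_equal(b$weights[rownames(a$weights), colnames(a$weights)], a$weights)
  perm <- c(3, 1, 2, 5, 4)
  fxp <- fx
  fxp$ep$values <- fx$ep$values[, perm]
  fxp$model$cell_T <- fx$model$cell_T[perm]
  p <- stage_network(fxp$ep, fxp$model, c("gA", "gB", "gC"), 0)
  expect_equal(p$weights, a$weights)
})
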