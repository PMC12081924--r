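# Shared fixture builders: small named matrices and hand-rolled oracles.

rand_expr <- function(n_genes, n_cells, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  storage.mode(m) <- "double"
  m
}

# brute-force local-scaling kernel: double loop computing rho, rho_bar,
# eps, W, P, S — independent of the vectorized implementation
oracle_kernel <- function(coords, k, mu) {
  n <- nrow(coords)
  rho <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    rho[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  nn <- lapply(1:n, function(i) setdiff(order(rho[i, ]), i)[1:k])
  rho_bar <- vapply(1:n, function(i) mean(rho[i, nn[[i]]]), 0)
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    eps <- max((rho_bar[i] + rho_bar[j] + rho[i, j]) / 3, 1e-12)
    W[i, j] <- exp(-rho[i, j]^2 / (mu * eps))
  }
  P <- matrix(0, n, n); S <- matrix(0, n, n)
  for (i in 1:n) {
    off <- sum(W[i, -i])
    for (j in 1:n) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * off)
    sn <- sum(W[i, nn[[i]]])
    for (j in nn[[i]]) S[i, j] <- W[i, j] / (2 * sn)
  }
  list(W = W, P = P, S = S)
}

# planted block affinity: high within-block weight, low across, light noise
planted_affinity <- function(n_blocks, per = 25, win = 0.8, across = 0.05,
                             noise = 0.02, seed = 1) {
  set.seed(seed)
  n <- n_blocks * per
  E <- matrix(across, n, n)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * per + 1):(b * per)
    E[idx, idx] <- win
  }
  E <- E + matrix(rnorm(n * n, 0, noise), n, n)
  E <- abs(E + t(E)) / 2
  diag(E) <- 0
  dimnames(E) <- list(sprintf("c%03d", 1:n), sprintf("c%03d", 1:n))
  E
}

# study configuration for the synthetic 400-gene panel (see the methods
# vignette): panel-scaled feature selection, full profile retention, eight
# stages
synthetic_study_config <- function(...) {
  scrden_config(n_clusters = 8, intrinsic_mean_min = 0.5,
                entropy_quantile = 0.60, cv_min_edges = 20000, ...)
}

# branch x time-bin reference partition for a simulation truth table
branch_bin_truth <- function(cell_info, t_branch = 0.4) {
  bin <- cut(cell_info$true_time, breaks = c(0, 0.25, 0.5, 0.75, 1),
             include.lowest = TRUE)
  grp <- ifelse(cell_info$true_time <= t_branch,
                paste0("root.", bin),
                paste0(cell_info$branch_label, ".", bin))
  stats::setNames(grp, cell_info$cell_id)
}
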