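#' Simulate branching single-cell expression data with known ground truth
#'
#' Generates a genes x cells count matrix from a latent pseudotime with an
#' optional branching structure, for exercising and validating every stage of
#' the pipeline without external data.
#'
#' Each cell draws a latent time `t ~ Uniform(0,1)` and a branch; before the
#' branch point `t_branch` all branches share one root expression program.
#' Genes are assigned to modules:
#' \describe{
#'   \item{ramp_up / ramp_down}{means sweep `m_lo` to `m_hi` (or back)
#'     log-linearly in `t`, shared by all branches;}
#'   \item{switch}{sigmoidal activation at a gene-specific switch time
#'     `t0 ~ Uniform(0.2, 0.8)` with steepness `steepness`. A switch gene
#'     whose `t0` lies past the branch point activates on a single branch
#'     (assigned round-robin) and stays at `m_lo` on the others — after a
#'     bifurcation, newly activating programs are lineage-specific;}
#'   \item{branch-specific (`branch<i>_up`)}{antagonistic lineage programs
#'     (only present when `n_branches > 1`): primed at an intermediate level
#'     `sqrt(m_lo * m_hi)` in the shared root, then resolving sigmoidally
#'     after the branch point — up to `m_hi` on the gene's own branch,
#'     silenced toward `m_lo` on the others (half-resolution a quarter of
#'     the way along the branch). This is the toggle-switch kinetics of
#'     mutually antagonistic fate regulators, which makes opposite-branch
#'     markers anti-correlated across the population as they are in real
#'     bifurcations;}
#'   \item{housekeeping}{constant moderate mean, no time trend;}
#'   \item{noise}{constant low mean.}
#' }
#' Counts are negative binomial with dispersion `size = nb_dispersion`
#' (variance `mu + mu^2/size`; large values approach Poisson). Dropout is
#' independent zero-inflation with probability
#' `dropout_rate * exp(-mu / 4)`, decreasing in the mean as technical
#' zeros do.
#'
#' The default mean range (0.5 to 50) and dispersion (5) describe strongly
#' dynamic developmental genes spanning about two orders of magnitude; under
#' these settings a ramp-up gene's Spearman correlation with true time
#' exceeds 0.8 at a few hundred cells, while housekeeping genes show none.
#'
#' @param n_genes,n_cells Matrix dimensions. `n_cells` must be at least
#'   `10 * n_branches`.
#' @param n_branches Number of terminal branches (1 = linear trajectory).
#' @param dropout_rate Base zero-inflation rate in `[0, 1)`. Default 0.2.
#' @param nb_dispersion Negative binomial `size`. Default 5.
#' @param seed Integer seed; the same seed reproduces the output bit for bit.
#' @param t_branch Branch point on the latent time axis. Default 0.4.
#' @param steepness Sigmoid steepness for switch-like genes. Default 10.
#' @param m_lo,m_hi Mean expression range for dynamic genes.
#' @return A list with `matrix` (genes x cells counts) and `truth`, a list of
#'   class `scrden_truth` holding `cell_info` (data frame: `cell_id`,
#'   `true_time`, `branch_label`), `module_assignment` (named character per
#'   gene) and `params`.
#' @examples
#' sim <- simulate_branching(n_genes = 50, n_cells = 60, n_branches = 2, seed = 1)
#' dim(sim$matrix)
#' table(sim$truth$module_assignment)
#' @export
simulate_branching <- function(n_genes = 400, n_cells = 300, n_branches = 2,
                               dropout_rate = 0.2, nb_dispersion = 5,
                               seed = 1L, t_branch = 0.4, steepness = 10,
                               m_lo = 0.5, m_hi = 50) {
  if (n_branches < 1) stop("'n_branches' must be >= 1", call. = FALSE)
  if (n_cells < 10 * n_branches)
    stop("'n_cells' must be at least 10 * n_branches", call. = FALSE)
  if (n_genes < 10) stop("'n_genes' must be at least 10", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("'dropout_rate' must lie in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))

  cell_id <- sprintf("cell%03d", seq_len(n_cells))
  tt <- runif(n_cells)
  branch <- sample(seq_len(n_branches), n_cells, replace = TRUE)
  branch_label <- ifelse(n_branches > 1 & tt <= t_branch, "root",
                         paste0("branch", branch))

  modules <- assign_modules(n_genes, n_branches)
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  t0 <- runif(n_genes, 0.2, 0.8)              # switch times
  sw_branch <- rep_len(seq_len(n_branches), n_genes)  # lineage of late switches
  hk_mean <- runif(n_genes, 1, 6)             # housekeeping levels
  noise_mean <- runif(n_genes, 0.2, 1)

  log_ratio <- log(m_hi / m_lo)
  ramp <- function(s) m_lo * exp(log_ratio * pmin(pmax(s, 0), 1))
  sig <- function(t, t0g) 1 / (1 + exp(-steepness * (t - t0g)))

  mu <- matrix(0, n_genes, n_cells, dimnames = list(gene_id, cell_id))
  post <- pmax(tt - t_branch, 0) / (1 - t_branch)   # progress past the branch point
  for (g in seq_len(n_genes)) {
    mod <- modules[g]
    mu[g, ] <- switch(
      sub("^branch[0-9]+_up$", "branch_up", mod),
      ramp_up = ramp(tt),
      ramp_down = ramp(1 - tt),
      switch = {
        on <- m_lo + (m_hi - m_lo) * sig(tt, t0[g])
        if (n_branches > 1 && t0[g] > t_branch) {
          ifelse(branch == sw_branch[g], on, m_lo)   # lineage-specific program
        } else on
      },
      housekeeping = rep(hk_mean[g], n_cells),
      noise = rep(noise_mean[g], n_cells),
      branch_up = {
        b <- as.integer(sub("^branch([0-9]+)_up$", "\\1", mod))
        m_mid <- sqrt(m_lo * m_hi)
        res <- sig(post, 0.25)                 # resolution after the branch point
        up <- m_mid + (m_hi - m_mid) * res
        down <- m_mid + (m_lo - m_mid) * res
        ifelse(tt <= t_branch, m_mid, ifelse(branch == b, up, down))
      },
      stop("unknown module: ", mod)
    )
  }

  counts <- matrix(rnbinom(n_genes * n_cells, size = nb_dispersion, mu = mu),
                   n_genes, n_cells, dimnames = dimnames(mu))
  if (dropout_rate > 0) {
    p_drop <- dropout_rate * exp(-mu / 4)
    drop <- matrix(rbinom(n_genes * n_cells, 1L, p_drop), n_genes, n_cells)
    counts[drop == 1L] <- 0
  }

  truth <- structure(list(
    cell_info = data.frame(cell_id = cell_id, true_time = tt,
                           branch_label = branch_label, branch = branch,
                           stringsAsFactors = FALSE),
    module_assignment = stats::setNames(modules, gene_id),
    params = list(n_genes = n_genes, n_cells = n_cells,
                  n_branches = n_branches, dropout_rate = dropout_rate,
                  nb_dispersion = nb_dispersion, seed = as.integer(seed),
                  t_branch = t_branch, steepness = steepness,
                  m_lo = m_lo, m_hi = m_hi)
  ), class = "scrden_truth")
  list(matrix = counts, truth = truth)
}

assign_modules <- function(n_genes, n_branches) {
  # proportions of the gene universe per module class
  prop <- c(ramp_up = 0.15, ramp_down = 0.15, switch = 0.15,
            housekeeping = 0.25, noise = 0.15, branch = 0.15)
  if (n_branches == 1) {                       # fold branch modules into ramps
    prop["ramp_up"] <- prop["ramp_up"] + prop["branch"]
    prop <- prop[names(prop) != "branch"]
  }
  counts <- floor(prop * n_genes)
  counts[1] <- counts[1] + n_genes - sum(counts)
  labels <- rep(names(counts), counts)
  if (n_branches > 1) {
    bidx <- which(labels == "branch")
    labels[bidx] <- paste0("branch",
                           rep_len(seq_len(n_branches), length(bidx)), "_up")
  }
  labels
}

#' Write a simulation to disk
#'
#' Writes the simulated matrix in either supported format plus a truth table
#' (`truth.tsv`: `cell_id`, `true_time`, `branch_label`).
#'
#' @param sim Result of [simulate_branching()].
#' @param dir Output directory (created if needed).
#' @param format `"dense"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, format = c("dense", "mtx")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "dense") {
    write_expression(sim$matrix, file.path(dir, "matrix.tsv"), "dense")
  } else {
    write_expression(sim$matrix, dir, "mtx")
  }
  write.table(sim$truth$cell_info[, c("cell_id", "true_time", "branch_label")],
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
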