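#' Pseudotemporal ordering score (POS)
#'
#' Measures how well an inferred cell ordering matches known collection
#' times. Every ordered pair `(i, j)` with `i` placed before `j` contributes
#' `(T(j) - T(i)) / D` (0 when the times are equal), and the normalizer `D`
#' is the maximum attainable sum — that of a time-sorted arrangement — so
#' the score is 1 exactly when the ordering is time-sorted, -1 when
#' reverse-sorted, and lies in `[-1, 1]` in between.
#'
#' @param order Character vector of cell identifiers in inferred order.
#' @param times Named numeric vector of collection times covering every cell
#'   in `order`.
#' @return POS in `[-1, 1]`; defined as 0 (with a warning) when all times
#'   are equal.
#' @examples
#' tm <- c(a = 1, b = 2, c = 3)
#' pos_score(c("a", "b", "c"), tm)   # 1
#' pos_score(c("c", "b", "a"), tm)   # -1
#' @export
pos_score <- function(order, times) {
  if (anyDuplicated(order)) stop("duplicate cells in the ordering", call. = FALSE)
  tv <- times[order]
  if (anyNA(tv)) stop("collection times missing for some cells", call. = FALSE)
  N <- length(tv)
  if (N < 2) stop("POS needs at least 2 cells", call. = FALSE)
  # sum over pairs i<j of (T[j] - T[i]) = sum_i T[i] * (2i - 1 - N)
  w <- 2 * seq_len(N) - 1 - N
  D <- sum(sort(tv) * w)
  if (D == 0) {
    warning("all collection times equal; POS defined as 0")
    return(0)
  }
  sum(tv * w) / D
}

#' Pairwise POS contribution
#'
#' The contribution of one cell pair to the POS sum: 0 when the two
#' collection times are equal, otherwise `(t_j - t_i) / D`.
#'
#' @param t_i,t_j Collection times of the earlier- and later-placed cell.
#' @param D Normalizer (the time-sorted pair sum). Default 1.
#' @return Numeric contribution.
#' @export
pos_pair_contribution <- function(t_i, t_j, D = 1) {
  if (t_i == t_j) 0 else (t_j - t_i) / D
}

#' Robust score between two cell orderings
#'
#' The fraction of unordered cell pairs of the union `U` of the two
#' orderings whose relative order agrees (concordant pairs score 1, all
#' others 0, including pairs involving a cell present in only one
#' ordering), normalized by `|U| (|U| - 1) / 2`. An ordering against itself
#' scores 1; against its reverse, 0.
#'
#' @param o1,o2 Character vectors of cell identifiers (orderings).
#' @return Score in `[0, 1]`.
#' @export
robust_score <- function(o1, o2) {
  if (anyDuplicated(o1) || anyDuplicated(o2))
    stop("orderings must be duplicate-free", call. = FALSE)
  U <- union(o1, o2)
  nU <- length(U)
  if (nU < 2) stop("need at least 2 cells in the union", call. = FALSE)
  p1 <- match(U, o1)
  p2 <- match(U, o2)
  d1 <- outer(p1, p1, `-`)
  d2 <- outer(p2, p2, `-`)
  conc <- !is.na(d1) & !is.na(d2) & (sign(d1) == sign(d2))
  ut <- upper.tri(conc)
  sum(conc[ut]) / (nU * (nU - 1) / 2)
}

#' Perturb an expression matrix with scaled Gaussian noise
#'
#' Adds to every (log-scale) entry of gene `g` independent
#' `Normal(0, (k_factor * sigma_g)^2)` noise, where `sigma_g` is that gene's
#' standard deviation across cells, then floors at 0. Constant genes are
#' unchanged; as `k_factor` shrinks the output approaches the input.
#'
#' @param X Genes x cells matrix (log scale).
#' @param k_factor Noise scale relative to each gene's sd (e.g. 0.05 for
#'   "5% noise").
#' @param seed Integer seed.
#' @return Perturbed matrix of the same shape.
#' @export
perturb_with_noise <- function(X, k_factor, seed = 1L) {
  if (k_factor <= 0) stop("'k_factor' must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  sg <- apply(X, 1, sd)
  noise <- matrix(rnorm(length(X)), nrow(X), ncol(X)) * (k_factor * sg)
  pmax(X + noise, 0)
}

#' Bubble sort index between two orderings
#'
#' `1 - inv / (n (n - 1) / 2)`, where `inv` is the number of adjacent swaps
#' bubble sort needs to turn one ordering into the other (the inversion
#' count). Identical orderings score 1, reversed orderings 0.
#'
#' @param o1,o2 Orderings over the same duplicate-free cell set.
#' @return Index in `[0, 1]`.
#' @export
bubble_sort_index <- function(o1, o2) {
  if (anyDuplicated(o1) || anyDuplicated(o2) || !setequal(o1, o2) ||
      length(o1) != length(o2))
    stop("orderings must be duplicate-free over the same cell set", call. = FALSE)
  v <- match(o2, o1)
  n <- length(v)
  inv <- sum(vapply(seq_len(n - 1),
                    function(i) sum(v[i] > v[(i + 1):n]), 0))
  1 - inv / (n * (n - 1) / 2)
}

#' Kendall correlation between two orderings
#'
#' Kendall's tau of the positions the common cells occupy in each ordering.
#' On duplicate-free orderings it equals `2 * BSI - 1`.
#'
#' @param o1,o2 Orderings over the same cell set.
#' @return Tau in `[-1, 1]`.
#' @export
kendall_order_cor <- function(o1, o2) {
  if (!setequal(o1, o2)) stop("orderings must cover the same cells", call. = FALSE)
  cor(match(o1, o1), match(o1, o2), method = "kendall")
}

#' Clustering agreement: ARI and NMI
#'
#' Adjusted Rand index and normalized mutual information (arithmetic-mean
#' normalization) between two labelings of the same cells.
#'
#' @param labels_a,labels_b Cluster labels; if both are named they are
#'   aligned by name.
#' @return Named numeric vector `c(ari = ..., nmi = ...)`.
#' @export
clustering_agreement <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("labelings cover different cell sets", call. = FALSE)
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop("labelings have different lengths", call. = FALSE)
  }
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  c(ari = igraph::compare(a, b, method = "adjusted.rand"),
    nmi = igraph::compare(a, b, method = "nmi"))
}
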