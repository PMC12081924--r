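#' Read a genes x cells expression matrix
#'
#' Reads a non-negative expression matrix either from a dense labelled
#' CSV/TSV table or from a MatrixMarket coordinate file with companion
#' feature and barcode label files (the 10x layout). The returned matrix is
#' always oriented genes x cells with gene identifiers as row names and cell
#' identifiers as column names.
#'
#' For dense input the first column holds the row identifiers. Rows are taken
#' to be genes unless `cells_as_rows = TRUE`, in which case the table is
#' transposed after reading. Missing entries are set to 0 and their count
#' reported; negative entries and duplicated identifiers are errors.
#'
#' For `format = "mtx"`, `path` may be either the `.mtx` file itself or a
#' directory containing `matrix.mtx`, `features.tsv` (or `genes.tsv`) and
#' `barcodes.tsv`. Gene identifiers come from the first column of the
#' features file.
#'
#' @param path File (dense or `.mtx`) or directory (10x layout).
#' @param format `"dense"` or `"mtx"`.
#' @param cells_as_rows Dense input only: rows are cells, so transpose.
#' @param features,barcodes Optional explicit paths to the label files for
#'   `format = "mtx"`.
#' @return Numeric matrix, genes x cells, with dimnames.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_expression(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("g", 1:3), paste0("c", 1:2))), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, format = c("dense", "mtx"),
                            cells_as_rows = FALSE,
                            features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
    if (ncol(dt) < 2) stop("dense matrix file needs an id column plus data: ", path,
                           call. = FALSE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (cells_as_rows) {
      m <- t(m)
      message("read_expression: input declared cells-as-rows; transposed to genes x cells")
    }
  } else {
    paths <- resolve_mtx_paths(path, features, barcodes)
    m <- as.matrix(Matrix::readMM(paths$matrix))
    storage.mode(m) <- "double"
    feats <- data.table::fread(paths$features, header = FALSE, data.table = FALSE)
    bcs <- data.table::fread(paths$barcodes, header = FALSE, data.table = FALSE)
    if (nrow(feats) != nrow(m))
      stop(sprintf("features file has %d entries but matrix has %d rows",
                   nrow(feats), nrow(m)), call. = FALSE)
    if (nrow(bcs) != ncol(m))
      stop(sprintf("barcodes file has %d entries but matrix has %d columns",
                   nrow(bcs), ncol(m)), call. = FALSE)
    rownames(m) <- as.character(feats[[1]])
    colnames(m) <- as.character(bcs[[1]])
  }
  validate_expression_matrix(m)
}

resolve_mtx_paths <- function(path, features, barcodes) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path, call. = FALSE)
    if (is.null(features)) {
      features <- file.path(path, "features.tsv")
      if (!file.exists(features)) features <- file.path(path, "genes.tsv")
    }
    if (is.null(barcodes)) barcodes <- file.path(path, "barcodes.tsv")
  } else {
    mtx <- path
    if (!file.exists(mtx)) stop("file not found: ", mtx, call. = FALSE)
    d <- dirname(mtx)
    if (is.null(features)) {
      features <- file.path(d, "features.tsv")
      if (!file.exists(features)) features <- file.path(d, "genes.tsv")
    }
    if (is.null(barcodes)) barcodes <- file.path(d, "barcodes.tsv")
  }
  for (f in c(features, barcodes))
    if (!file.exists(f)) stop("companion label file not found: ", f, call. = FALSE)
  list(matrix = mtx, features = features, barcodes = barcodes)
}

#' Validate an expression matrix
#'
#' Checks the invariants every pipeline stage relies on: numeric matrix with
#' duplicate-free gene and cell identifiers, no negative entries; missing
#' entries are set to 0 with a message.
#'
#' @param m Matrix to validate.
#' @return The validated (possibly NA-filled) matrix, invisibly classed as a
#'   plain matrix.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene row names and cell column names", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers: ",
         paste(head(unique(rownames(m)[duplicated(rownames(m))]), 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell identifiers: ",
         paste(head(unique(colnames(m)[duplicated(colnames(m))]), 5), collapse = ", "),
         call. = FALSE)
  n_na <- sum(is.na(m))
  if (n_na > 0) {
    m[is.na(m)] <- 0
    message(sprintf("validate_expression_matrix: %d missing entries set to 0", n_na))
  }
  if (any(m < 0))
    stop("expression matrix has negative entries", call. = FALSE)
  m
}

#' Write a genes x cells expression matrix
#'
#' Inverse of [read_expression()]. Dense output is a labelled CSV/TSV with
#' genes as rows (values printed at full precision so that a read round-trip
#' is exact); `format = "mtx"` writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` into the directory `path`.
#'
#' @param m Genes x cells matrix with dimnames.
#' @param path Output file (dense) or directory (mtx).
#' @param format `"dense"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("dense", "mtx")) {
  format <- match.arg(format)
  m <- validate_expression_matrix(m)
  if (format == "dense") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    df <- data.frame(gene_id = rownames(m), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", colnames(m))
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Write a weighted gene network as an edge list
#'
#' Writes tab-separated rows `gene_a  gene_b  weight` (plus any further edge
#' attribute columns), with each pair ordered lexicographically and rows
#' sorted, so the file is a canonical representation of the graph. An empty
#' graph yields a header-only file.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight` and
#'   optional extra attribute columns, or an object with an `$edges`
#'   component of that shape (e.g. a [build_coexpression_graph()] result,
#'   with its `abs_r` used as the weight).
#' @param path Output TSV path.
#' @param digits Significant digits for numeric columns. Default 10.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, digits = 10) {
  if (!is.data.frame(edges)) {
    if (!is.null(edges$edges)) {
      edges <- edges$edges
      if (!"weight" %in% names(edges) && "abs_r" %in% names(edges))
        edges$weight <- edges$abs_r
    } else stop("'edges' must be a data frame or carry an $edges component",
                call. = FALSE)
  }
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(edges)))
    stop("edge table needs columns gene_a, gene_b, weight", call. = FALSE)
  if (nrow(edges)) {
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  }
  out <- edges
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf(paste0("%.", digits, "g"), out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list network written by [write_network()]
#'
#' @param path TSV path.
#' @return Data frame with at least `gene_a`, `gene_b`, `weight`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("gene_a", "gene_b")))
  if (!all(c("gene_a", "gene_b", "weight") %in% names(df)))
    stop("not an edge-list file (expected gene_a, gene_b, weight): ", path,
         call. = FALSE)
  df
}
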