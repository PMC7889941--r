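## Expression input: dense tables, sparse (MTX) single-cell counts,
## annotations, cluster averaging and restriction to database genes.
## An expression matrix is a plain numeric gene-by-sample matrix with unique
## dimnames; annotations travel separately as named character vectors
## (sample_id -> label), in the style of limma's targets frame.

#' Validate a gene-by-sample expression matrix
#'
#' @param m numeric matrix, genes in rows, samples in columns.
#' @return The matrix, invisibly, after checking non-negativity and unique
#'   non-empty dimnames.
#' @export
check_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicated gene symbols in expression matrix")
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample ids in expression matrix")
  if (anyNA(m))
    stop("expression matrix contains missing values")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value for gene '%s', sample '%s'",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  invisible(m)
}

#' Read a gene-by-sample expression table
#'
#' Delimited text; first column holds gene symbols, header holds sample ids.
#' Duplicate gene rows are resolved by keeping the row with the largest row
#' sum (deterministic, order-independent), with a warning.
#'
#' @param path file path.
#' @param sep separator; guessed (tab vs comma) when NULL.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- trimws(as.character(tab[[1]]))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) & !anyNA(v))
        stop(sprintf("non-numeric value in column '%s'", names(vals)[j]))
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("%d duplicated gene symbol(s) (%s ...): keeping the row with the largest total signal",
                    length(dup), dup[1]))
    ord <- order(rowSums(m), decreasing = TRUE)
    m <- m[ord, , drop = FALSE]
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
    m <- m[order(match(rownames(m), genes)), , drop = FALSE]
  }
  check_expression_matrix(m)
  m
}

#' Write a gene-by-sample expression table
#'
#' Inverse of \code{\link{read_expression_table}}.
#' @param m numeric matrix.
#' @param path output path.
#' @param sep separator.
#' @export
write_expression_table <- function(m, path, sep = "\t") {
  check_expression_matrix(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sparse single-cell counts (MatrixMarket triplet + label files)
#'
#' @param matrix_path MTX coordinate file (genes x cells).
#' @param genes_path,cells_path one label per line, matching the MTX
#'   dimensions.
#' @param dense return a dense base matrix (default) or a dgCMatrix.
#' @return Gene-by-cell matrix; entries absent from the triplet are zero.
#' @export
read_sparse_counts <- function(matrix_path, genes_path, cells_path,
                               dense = TRUE) {
  sm <- Matrix::readMM(matrix_path)
  # writeMM emits "pattern" files for binary/empty matrices; read those
  # back as numeric
  if (methods::is(sm, "nMatrix")) sm <- methods::as(sm, "dMatrix")
  sm <- methods::as(sm, "generalMatrix")  # symmetric storage would break dimnames
  genes <- trimws(readLines(genes_path))
  cells <- trimws(readLines(cells_path))
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  if (nrow(sm) != length(genes))
    stop(sprintf("gene label file has %d entries but matrix has %d rows",
                 length(genes), nrow(sm)))
  if (ncol(sm) != length(cells))
    stop(sprintf("cell label file has %d entries but matrix has %d columns",
                 length(cells), ncol(sm)))
  dimnames(sm) <- list(genes, cells)
  if (dense) {
    m <- as.matrix(sm)
    storage.mode(m) <- "double"
    check_expression_matrix(m)
    m
  } else methods::as(sm, "CsparseMatrix")
}

#' Write sparse counts as an MTX triplet plus label files
#' @param m gene-by-cell matrix (dense or sparse).
#' @param matrix_path,genes_path,cells_path output paths.
#' @export
write_sparse_counts <- function(m, matrix_path, genes_path, cells_path) {
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sm, matrix_path)
  writeLines(rownames(m), genes_path)
  writeLines(colnames(m), cells_path)
  invisible(matrix_path)
}

#' Read a two-column annotation table (sample_id, label)
#' @param path delimited text with a header.
#' @param sep separator; guessed when NULL.
#' @return Named character vector: names are sample/cell ids.
#' @export
read_annotation <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("annotation needs at least two columns")
  stats::setNames(as.character(tab[[2]]), trimws(as.character(tab[[1]])))
}

#' Average single cells into cluster profiles
#'
#' Collapses a gene-by-cell matrix to a gene-by-cluster matrix of arithmetic
#' means, the standard remedy for single-cell sparsity before communication
#' scoring. Cells present in the matrix but absent from the assignment are
#' ignored with a warning; an assignment naming a missing cell is an error.
#'
#' @param m gene-by-cell matrix.
#' @param assignment named character vector: cell_id -> cluster label.
#' @return Gene-by-cluster matrix; attribute \code{"n_cells"} gives member
#'   counts per cluster.
#' @export
cluster_average <- function(m, assignment) {
  check_expression_matrix(m)
  if (is.null(names(assignment)))
    stop("assignment must be a named vector (cell_id -> cluster)")
  unknown <- setdiff(names(assignment), colnames(m))
  if (length(unknown) > 0)
    stop("assignment references cells absent from the matrix: ",
         paste(head(unknown, 3), collapse = ", "))
  unassigned <- setdiff(colnames(m), names(assignment))
  if (length(unassigned) > 0)
    warning(sprintf("%d cell(s) without cluster assignment ignored",
                    length(unassigned)))
  clusters <- sort(unique(assignment))
  out <- vapply(clusters, function(cl) {
    cells <- names(assignment)[assignment == cl]
    rowMeans(m[, cells, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), clusters))
  attr(out, "n_cells") <- stats::setNames(
    as.integer(table(factor(assignment, levels = clusters))), clusters)
  out
}

#' Restrict an expression matrix to the genes of a database
#'
#' Keeps the rows found in \code{gene_universe(db)} and reports database
#' genes the platform did not capture (these interactions will be excluded
#' from scoring rather than zeroed).
#'
#' @param m gene-by-sample matrix.
#' @param db an \code{lr_database}.
#' @return The restricted matrix; attribute \code{"missing_genes"} lists
#'   database genes absent from the matrix.
#' @export
restrict_to_database_genes <- function(m, db) {
  check_expression_matrix(m)
  universe <- gene_universe(db)
  keep <- intersect(rownames(m), universe)
  if (length(keep) == 0)
    stop("no database gene found in the expression matrix: nothing to score")
  out <- m[keep, , drop = FALSE]
  attr(out, "missing_genes") <- setdiff(universe, rownames(m))
  out
}
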