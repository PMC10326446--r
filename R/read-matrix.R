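#' Read a 10x-style Matrix Market expression directory
#'
#' Expects the 10x Genomics convention: a directory holding a Matrix Market
#' coordinate file (`matrix.mtx`, optionally gzipped), a features/genes file
#' (first column = gene identifier, optional second column = symbol) and a
#' barcodes file, one entry per line. Returns the matrix in genes-by-cells
#' orientation with unique dimnames; duplicated gene identifiers are
#' disambiguated by suffixing (`".1"`, `".2"`, ...) with a warning.
#'
#' @param dir Path to the directory.
#' @param use_symbols If the features file has two or more columns, use the
#'   second (gene symbol) column as rownames instead of the first.
#' @return A sparse `dgCMatrix`, genes in rows, cells in columns.
#' @export
read_expression_mtx <- function(dir, use_symbols = TRUE) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  find1 <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    stop("no ", stems[1], "[.gz] (or equivalent) in ", dir, call. = FALSE)
  }
  mtx_path <- find1(c("matrix.mtx"))
  feat_path <- find1(c("features.tsv", "genes.tsv"))
  bc_path <- find1(c("barcodes.tsv"))

  m <- Matrix::readMM(mtx_path)
  m <- as(m, "CsparseMatrix")
  if (any(m@x < 0)) stop("expression matrix contains negative values", call. = FALSE)

  feats <- read.delim(feat_path, header = FALSE, colClasses = "character")
  bcs <- readLines(bc_path, warn = FALSE)
  bcs <- bcs[nzchar(bcs)]
  if (nrow(feats) != nrow(m)) {
    stop("features file has ", nrow(feats), " entries but matrix header declares ",
         nrow(m), " rows", call. = FALSE)
  }
  if (length(bcs) != ncol(m)) {
    stop("barcodes file has ", length(bcs), " entries but matrix header declares ",
         ncol(m), " columns", call. = FALSE)
  }
  ids <- if (use_symbols && ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning(length(dup), " duplicated gene identifier(s) made unique by suffixing: ",
            paste(head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ...", call. = FALSE)
    ids <- make.unique(ids, sep = ".")
  }
  if (anyDuplicated(bcs)) stop("duplicated cell barcodes", call. = FALSE)
  dimnames(m) <- list(ids, bcs)
  validate_expression(m)
}

#' Read a dense CSV expression matrix
#'
#' @param path CSV file with row and column names.
#' @param genes_in_rows Orientation flag; the matrix is returned
#'   genes-by-cells either way. Default assumes genes in rows.
#' @return A sparse `dgCMatrix`, genes in rows, cells in columns.
#' @export
read_expression_csv <- function(path, genes_in_rows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as(as.matrix(df), "CsparseMatrix")
  if (!genes_in_rows) m <- Matrix::t(m)
  validate_expression(m)
}

#' Validate a genes-by-cells expression matrix
#'
#' Checks the invariants the annotation pipeline relies on: a non-empty
#' sparse matrix of non-negative values with unique gene and cell
#' identifiers as dimnames.
#'
#' @param x A matrix or sparse Matrix, genes in rows.
#' @return The matrix as a validated `dgCMatrix` (invisibly usable in
#'   pipes).
#' @export
validate_expression <- function(x) {
  if (!is(x, "CsparseMatrix")) x <- as(as(x, "sparseMatrix"), "CsparseMatrix")
  if (nrow(x) < 1 || ncol(x) < 1) stop("matrix must have >=1 gene and >=1 cell", call. = FALSE)
  if (any(x@x < 0)) stop("expression values must be non-negative", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("matrix must carry gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("gene identifiers must be unique", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("cell identifiers must be unique", call. = FALSE)
  x
}

#' Write a simulated or real expression matrix as a 10x-style directory
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` (uncompressed) so
#' the result round-trips through [read_expression_mtx()].
#'
#' @param x Genes-by-cells matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(x, dir) {
  x <- validate_expression(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x, file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = rownames(x), symbol = rownames(x)),
              file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
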