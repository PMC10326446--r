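## shared fixture builders; everything is generated in code at test time

## small sparse count matrix with dimnames
toy_matrix <- function(n_genes = 30, n_cells = 12, seed = 1, density = 0.5) {
  set.seed(seed)
  x <- Matrix::rsparsematrix(n_genes, n_cells, density,
                             rand.x = function(n) stats::rpois(n, 4) + 1)
  dimnames(x) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("c%03d", seq_len(n_cells)))
  methods::as(x, "CsparseMatrix")
}

## two perfectly separable populations: group A expresses only genes 1..10,
## group B only genes 11..20 (plus shared housekeeping background)
separable_matrix <- function(n_per_group = 10, seed = 1) {
  set.seed(seed)
  n_genes <- 30
  n <- 2 * n_per_group
  m <- matrix(0, n_genes, n)
  m[21:30, ] <- rpois(10 * n, 3) + 1                      # shared background
  m[1:10, seq_len(n_per_group)] <- rpois(10 * n_per_group, 8) + 1
  m[11:20, n_per_group + seq_len(n_per_group)] <- rpois(10 * n_per_group, 8) + 1
  dimnames(m) <- list(sprintf("G%03d", 1:n_genes), sprintf("c%03d", 1:n))
  methods::as(methods::as(m, "sparseMatrix"), "CsparseMatrix")
}

separable_sets <- function() {
  gene_sets(A = sprintf("G%03d", 1:10), B = sprintf("G%03d", 11:20))
}

## write a 3x2 MTX fixture directory; entries (1,1)=5, (3,2)=2
write_toy_mtx_dir <- function(dir = withr_tempdir(),
                              features = c("GENE1", "GENE2", "GENE3"),
                              barcodes = c("AAAC", "AAAG")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(paste(features, features, sep = "\t"), file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}

withr_tempdir <- function() {
  d <- tempfile("fix")
  dir.create(d)
  d
}

## brute-force oracle: the nested double sum over the binary membership
## sequence, evaluated literally
double_sum_score <- function(ranked_gene_ids, positive) {
  s <- as.integer(ranked_gene_ids %in% positive)
  sum(cumsum(s))
}

## O(M^2) pairwise-difference Gini oracle
pairwise_gini <- function(v) {
  v[v < 0] <- 0
  M <- length(v)
  if (mean(v) == 0) return(NA_real_)
  sum(abs(outer(v, v, `-`))) / (2 * M^2 * mean(v))
}

## O(n^2) pair-metric oracle by full enumeration of cell pairs
enumerate_pair_metrics <- function(truth, pred) {
  n <- length(truth)
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]
    sp <- pred[i] == pred[j]
    if (st && sp) tp <- tp + 1
    else if (!st && sp) fp <- fp + 1
    else if (!st && !sp) tn <- tn + 1
    else fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       f1 = 2 * tp / (2 * tp + fp + fn))
}
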