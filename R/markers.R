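#' Infer marker gene sets by one-vs-rest Wilcoxon rank-sum tests
#'
#' For each cell type, every gene is tested for higher expression in that
#' type versus all other cells with a two-sided Wilcoxon rank-sum test on
#' `log1p` library-size-scaled expression (counts per 10,000). Genes are
#' kept when (i) at least `min_fraction` of the type's cells express them,
#' (ii) the log2 fold change of pseudocounted mean normalised expression,
#' `log2((mean_in + 1) / (mean_out + 1))`, is at least `min_logfc`, and
#' (iii) the shift is positive. Survivors are ranked by p-value (ties
#' broken by fold change) and the `top_n` genes per type become that
#' type's positive marker set.
#'
#' The test statistic uses the normal approximation with the exact
#' tie-correction term (zero counts form one large tie block), matching
#' `stats::wilcox.test(exact = FALSE, correct = FALSE)`.
#'
#' @param x Genes-by-cells count matrix.
#' @param types Character vector of cell-type labels, one per cell.
#' @param min_fraction Minimum expressing-cell fraction within the type,
#'   default 0.1.
#' @param min_logfc Minimum log2 fold change, default 0.5.
#' @param top_n Markers per type, default 100. Types with fewer passing
#'   genes return what passes, with a warning.
#' @param quiet Suppress the short-list warning.
#' @return A [gene_sets()] collection, one entry per type (sorted type
#'   order), positive markers only.
#' @export
infer_markers <- function(x, types, min_fraction = 0.1, min_logfc = 0.5,
                          top_n = 100, quiet = FALSE) {
  x <- validate_expression(x)
  if (length(types) != ncol(x)) {
    stop("types must have one label per cell", call. = FALSE)
  }
  ut <- sort(unique(types))
  if (length(ut) < 2) stop("need at least 2 cell types", call. = FALSE)
  if (min(table(types)) < 3) stop("every type needs at least 3 cells", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1) stop("min_fraction must be in (0, 1]",
                                                  call. = FALSE)
  n <- ncol(x); G <- nrow(x)

  norm <- x %*% Diagonal(x = 1e4 / Matrix::colSums(x))
  norm@x <- log1p(norm@x)
  tn <- as(Matrix::t(norm), "CsparseMatrix")  # cells x genes: gene-major slices
  rm(norm)
  nz_per_gene <- diff(tn@p)
  n0 <- n - nz_per_gene
  type_of <- match(types, ut)
  K <- length(ut)

  ## per-gene statistics, computed over gene chunks to bound memory
  cnt_gt <- matrix(0, G, K)
  rsum_gt <- matrix(0, G, K)
  esum_gt <- matrix(0, G, K)
  tie_term <- as.numeric(n0)^3 - n0   # zero block; non-zero ties added below
  chunk <- 2000L
  for (g0 in seq(1L, G, by = chunk)) {
    g1 <- min(g0 + chunk - 1L, G)
    idx <- (tn@p[g0] + 1L):(tn@p[g1 + 1L])
    if (tn@p[g1 + 1L] == tn@p[g0]) next
    ng <- g1 - g0 + 1L
    gene <- rep.int(seq_len(ng), nz_per_gene[g0:g1])
    cell <- tn@i[idx] + 1L
    val <- tn@x[idx]
    r <- grouped_midrank(val, gene, ng)
    tie_term[g0:g1] <- tie_term[g0:g1] + grouped_tie_term(val, gene, ng)
    bin <- gene + ng * (type_of[cell] - 1L)
    cnt <- group_sum(rep(1, length(bin)), bin, ng * K)
    rs <- group_sum(r, bin, ng * K)
    es <- group_sum(expm1(val), bin, ng * K)
    cnt_gt[g0:g1, ] <- matrix(cnt, ng, K)
    rsum_gt[g0:g1, ] <- matrix(rs, ng, K)
    esum_gt[g0:g1, ] <- matrix(es, ng, K)
  }
  rm(tn); gc(FALSE)
  esum_tot <- rowSums(esum_gt)

  n_by_type <- tabulate(type_of, nbins = K)
  entries <- list()
  for (k in seq_len(K)) {
    n1 <- n_by_type[k]; n2 <- n - n1
    cnt <- cnt_gt[, k]
    frac <- cnt / n1
    m1 <- esum_gt[, k] / n1
    m2 <- (esum_tot - esum_gt[, k]) / n2
    lfc <- log2(m1 + 1) - log2(m2 + 1)
    ## group rank sum: zeros share midrank (n0 + 1) / 2, non-zeros rank n0 + r
    R1 <- (n1 - cnt) * (n0 + 1) / 2 + cnt * n0 + rsum_gt[, k]
    U <- R1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    s2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z <- ifelse(s2 > 0, (U - mu) / sqrt(s2), 0)
    pval <- 2 * pnorm(-abs(z))
    keep <- which(frac >= min_fraction & lfc >= min_logfc & z > 0)
    ord <- keep[order(pval[keep], -lfc[keep])]
    if (length(ord) < top_n && !quiet) {
      warning("type '", ut[k], "': only ", length(ord),
              " genes pass the marker filters (requested ", top_n, ")",
              call. = FALSE)
    }
    entries[[ut[k]]] <- rownames(x)[head(ord, top_n)]
  }
  gene_sets(.list = entries)
}

## sum of (t^3 - t) over runs of equal values within each group
grouped_tie_term <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  if (length(x) == 0) return(out)
  o <- order(group, x, method = "radix")
  gx <- x[o]; gg <- group[o]
  new_run <- c(TRUE, gx[-1] != gx[-length(gx)] | gg[-1] != gg[-length(gg)])
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  per_run <- as.numeric(len)^3 - len
  first_of_run <- which(new_run)
  s <- rowsum(per_run, gg[first_of_run])
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
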