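#' Simulate an scRNA-seq count matrix with known cell types
#'
#' A gamma-Poisson hierarchy in the style of the standard scRNA-seq count
#' simulators: each gene draws a base mean from a Gamma distribution, with
#' a small fraction of high-expression outlier genes (median-multiple
#' log-normal factors); for each cell type a random subset of genes
#' (probability `de_prob`) is differentially expressed, with a log-normal
#' multiplicative factor that is inverted for half of the DE genes
#' (equally many up- and down-regulated); each cell draws an expected
#' library size from a log-normal; the per-gene, per-cell expected count
#' `lib_c * mean_(g,type) / sum_g mean_(g,type)` is then over-dispersed by
#' gamma mixing with a biological coefficient of variation
#' `bcv_common + 1 / sqrt(expected count)` (inverse-chi-square scaled
#' across genes), and counts are Poisson — i.e. marginally negative
#' binomial. Cell-type proportions are sampled from a uniform distribution
#' and renormalised. The defaults mirror the common simulator defaults:
#' 10,000 genes, `de_prob` 0.1, DE factor log-normal(0.1, 0.4), library
#' size log-normal(11, 0.2), gene mean Gamma(shape 0.6, rate 0.3),
#' outliers at probability 0.05 with log-normal(4, 0.5) factors, BCV
#' common 0.1 with 60 degrees of freedom.
#'
#' @param n_cells Number of cells.
#' @param n_types Number of cell types.
#' @param n_genes Number of genes, default 10000.
#' @param seed Integer seed; the whole draw is reproducible from it.
#' @param de_prob Per-gene, per-type probability of differential expression.
#' @param de_loc,de_scale Location and scale of the log-normal DE factor.
#' @param lib_loc,lib_scale Location and scale of the log-normal expected
#'   library size.
#' @param gamma_shape,gamma_rate Gamma parameters of the gene base mean.
#' @param outlier_prob,outlier_loc,outlier_scale Probability and log-normal
#'   location/scale of high-expression outlier genes (median multiples).
#' @param bcv_common,bcv_df Biological coefficient of variation: common
#'   level and inverse-chi-square degrees of freedom; `bcv_common = 0`
#'   disables over-dispersion (pure Poisson counts).
#' @param proportions Optional fixed cell-type proportions (positive,
#'   summing to 1); by default sampled uniformly.
#' @param gene_params Optional shared gene-level ground truth from
#'   [draw_gene_params()]. Replicate datasets of one benchmark must share
#'   it, so that "Type1" means the same transcriptional program in every
#'   replicate and markers learned on one dataset transfer to the others;
#'   `NULL` draws fresh parameters from `seed`.
#' @return A `sim_truth` object: list with `counts` (sparse genes x cells),
#'   `cell_info` (tibble `cell_id`, `type`), `de_factors` (genes x types
#'   matrix), `proportions`, and the `config`.
#' @seealso [simulate_replicates()] for a set of datasets sharing their
#'   gene-level ground truth.
#' @export
simulate_counts <- function(n_cells, n_types, n_genes = 10000, seed = 1,
                            de_prob = 0.1, de_loc = 0.1, de_scale = 0.4,
                            lib_loc = 11, lib_scale = 0.2,
                            gamma_shape = 0.6, gamma_rate = 0.3,
                            outlier_prob = 0.05, outlier_loc = 4,
                            outlier_scale = 0.5,
                            bcv_common = 0.1, bcv_df = 60,
                            proportions = NULL, gene_params = NULL) {
  stopifnot(n_cells >= n_types, n_types >= 1, n_genes >= 1)
  if (is.null(gene_params)) {
    gene_params <- draw_gene_params(n_genes, n_types, seed = seed,
                                    de_prob = de_prob, de_loc = de_loc,
                                    de_scale = de_scale,
                                    gamma_shape = gamma_shape,
                                    gamma_rate = gamma_rate,
                                    outlier_prob = outlier_prob,
                                    outlier_loc = outlier_loc,
                                    outlier_scale = outlier_scale,
                                    bcv_common = bcv_common, bcv_df = bcv_df)
  }
  if (length(gene_params$base_mean) != n_genes ||
      ncol(gene_params$de_factors) != n_types) {
    stop("gene_params dimensions do not match n_genes/n_types", call. = FALSE)
  }
  base_mean <- gene_params$base_mean
  de_factors <- gene_params$de_factors
  set.seed(seed)
  if (is.null(proportions)) {
    proportions <- runif(n_types)
    proportions <- proportions / sum(proportions)
  } else {
    if (length(proportions) != n_types || any(proportions <= 0)) {
      stop("proportions must be ", n_types, " positive values", call. = FALSE)
    }
    proportions <- proportions / sum(proportions)
  }
  sizes <- as.vector(rmultinom(1, n_cells, proportions))
  while (any(sizes == 0)) sizes <- as.vector(rmultinom(1, n_cells, proportions))
  libs <- exp(rnorm(n_cells, lib_loc, lib_scale))
  type_of_cell <- rep.int(seq_len(n_types), sizes)

  ## dense gamma-Poisson draws are made in cell blocks to bound memory
  bcv_chisq <- gene_params$bcv_chisq
  cols <- vector("list", n_types)
  block <- 500L
  for (t in seq_len(n_types)) {
    m <- base_mean * de_factors[, t]
    m <- m / sum(m)
    idx <- which(type_of_cell == t)
    pieces <- lapply(seq(1L, length(idx), by = block), function(b0) {
      b1 <- min(b0 + block - 1L, length(idx))
      lam <- outer(m, libs[idx[b0:b1]])
      if (bcv_common > 0) {
        ## biological over-dispersion: gamma mixing of the expected count
        bcv <- (bcv_common + 1 / sqrt(lam)) * bcv_chisq
        shape <- 1 / bcv^2
        lam <- matrix(rgamma(length(lam), shape = shape, scale = lam / shape),
                      nrow = n_genes)
      }
      as(as(matrix(rpois(length(lam), lam), nrow = n_genes), "sparseMatrix"),
         "CsparseMatrix")
    })
    cols[[t]] <- do.call(cbind, pieces)
  }
  counts <- do.call(cbind, cols)
  gene_ids <- sprintf("Gene%05d", seq_len(n_genes))
  cell_ids <- sprintf("Cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(gene_ids, cell_ids)
  rownames(de_factors) <- gene_ids
  structure(
    list(counts = counts,
         cell_info = tibble(cell_id = cell_ids,
                            type = paste0("Type", type_of_cell)),
         de_factors = de_factors,
         proportions = proportions,
         config = list(n_cells = n_cells, n_types = n_types, n_genes = n_genes,
                       seed = seed, de_prob = de_prob, de_loc = de_loc,
                       de_scale = de_scale, lib_loc = lib_loc,
                       lib_scale = lib_scale, gamma_shape = gamma_shape,
                       gamma_rate = gamma_rate, outlier_prob = outlier_prob,
                       outlier_loc = outlier_loc,
                       outlier_scale = outlier_scale,
                       bcv_common = bcv_common, bcv_df = bcv_df)),
    class = "sim_truth"
  )
}

#' Draw the gene-level ground truth of a simulated experiment
#'
#' The gene-level parameters — per-gene base mean (Gamma) and the per-type
#' differential-expression factors (log-normal, half inverted) — define
#' what the simulated cell types *are*. Datasets meant as replicates of
#' one experiment share a single draw of these parameters and differ only
#' in cells, proportions, library sizes and Poisson noise.
#'
#' @inheritParams simulate_counts
#' @return A list with `base_mean` (length `n_genes`), `de_factors`
#'   (`n_genes` x `n_types`) and `bcv_chisq` (per-gene inverse-chi-square
#'   scaling of the biological coefficient of variation).
#' @export
draw_gene_params <- function(n_genes, n_types, seed = 1,
                             de_prob = 0.1, de_loc = 0.1, de_scale = 0.4,
                             gamma_shape = 0.6, gamma_rate = 0.3,
                             outlier_prob = 0.05, outlier_loc = 4,
                             outlier_scale = 0.5,
                             bcv_common = 0.1, bcv_df = 60) {
  set.seed(seed)
  base_mean <- rgamma(n_genes, shape = gamma_shape, rate = gamma_rate)
  is_outlier <- runif(n_genes) < outlier_prob
  if (any(is_outlier)) {
    base_mean[is_outlier] <-
      stats::median(base_mean) * exp(rnorm(sum(is_outlier), outlier_loc,
                                           outlier_scale))
  }
  de_factors <- matrix(1, n_genes, n_types,
                       dimnames = list(NULL, paste0("Type", seq_len(n_types))))
  for (t in seq_len(n_types)) {
    is_de <- runif(n_genes) < de_prob
    f <- exp(rnorm(n_genes, de_loc, de_scale))
    down <- runif(n_genes) < 0.5
    f[down] <- 1 / f[down]
    de_factors[is_de, t] <- f[is_de]
  }
  bcv_chisq <- sqrt(bcv_df / stats::rchisq(n_genes, df = bcv_df))
  list(base_mean = base_mean, de_factors = de_factors, bcv_chisq = bcv_chisq)
}

#' Simulate replicate datasets sharing one gene-level ground truth
#'
#' Draws the gene-level parameters once ([draw_gene_params()]) and then
#' simulates `n_datasets` independent datasets from them, each with its
#' own uniformly sampled cell-type proportions, library sizes and counts.
#' This is the input expected by [run_benchmark()]: markers inferred on
#' one replicate are meaningful for the others because the cell types
#' share their transcriptional programs.
#'
#' @param n_datasets Number of replicate datasets.
#' @inheritParams simulate_counts
#' @return A list of `n_datasets` `sim_truth` objects.
#' @export
simulate_replicates <- function(n_datasets, n_cells, n_types,
                                n_genes = 10000, seed = 1, ...) {
  stopifnot(n_datasets >= 1)
  dots <- list(...)
  gene_arg_names <- c("de_prob", "de_loc", "de_scale", "gamma_shape",
                      "gamma_rate", "outlier_prob", "outlier_loc",
                      "outlier_scale", "bcv_common", "bcv_df")
  cell_arg_names <- c("lib_loc", "lib_scale", "proportions", "bcv_common")
  unknown <- setdiff(names(dots), c(gene_arg_names, cell_arg_names))
  if (length(unknown) > 0) {
    stop("unknown simulation arguments: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gp <- do.call(draw_gene_params,
                c(list(n_genes = n_genes, n_types = n_types, seed = seed),
                  dots[names(dots) %in% gene_arg_names]))
  lapply(seq_len(n_datasets), function(i) {
    do.call(simulate_counts,
            c(list(n_cells = n_cells, n_types = n_types, n_genes = n_genes,
                   seed = (seed %% 2000000L) * 1000L + i, gene_params = gp),
              dots[names(dots) %in% cell_arg_names]))
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells, ",
      x$config$n_types, " types\n", sep = "")
  print(table(x$cell_info$type))
  invisible(x)
}

#' Write a simulated dataset as a 10x-style directory plus a truth table
#'
#' @param sim A `sim_truth`.
#' @param dir Output directory; the counts go to `dir/` (`matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`) and the labels to `dir/truth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_truth"))
  write_expression_mtx(sim$counts, dir)
  write.table(as.data.frame(sim$cell_info), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
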