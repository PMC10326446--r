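#' Rank a cell's non-zero genes from high to low expression
#'
#' The assignment score is a rank statistic: only the identity and relative
#' order of a cell's expressed (non-zero) genes matter, never the units.
#' Genes are ranked 1 (highest expression) to N (lowest, N = number of
#' non-zero genes); tied expression values share their midrank, so the
#' result does not depend on the input order of genes.
#'
#' @param expr Numeric vector of non-negative expression values for one
#'   cell, named by gene identifier (or with `gene_ids` supplied).
#' @param gene_ids Gene identifiers, if `expr` is unnamed.
#' @return A tibble with columns `gene_id` and `rank`, one row per
#'   non-zero gene, ordered by rank; attribute `N` = number of non-zero
#'   genes. An all-zero cell yields zero rows with `N = 0`.
#' @export
rank_nonzero <- function(expr, gene_ids = names(expr)) {
  if (length(gene_ids) != length(expr)) {
    stop("gene_ids must have the same length as expr", call. = FALSE)
  }
  if (any(expr < 0)) stop("expression values must be non-negative", call. = FALSE)
  nz <- which(expr > 0)
  v <- expr[nz]
  r <- rank(-v, ties.method = "average")
  out <- tibble(gene_id = unname(gene_ids[nz][order(r)]),
                rank = unname(sort(r)))
  attr(out, "N") <- length(nz)
  out
}

#' Raw assignment score of one gene set for one cell
#'
#' The score is built from a binary marker-membership sequence along the
#' cell's ranked non-zero genes: nested partial cumulative sums of that
#' sequence are summed, so markers near the top of the ranking contribute
#' most. In closed form each expressed marker at rank r contributes
#' `N - r + 1`, giving `S = sum(N - r + 1)` over expressed markers; a cell
#' expressing no marker of the set scores 0.
#'
#' @param profile A ranked profile from [rank_nonzero()].
#' @param positive Character vector of the set's positive marker genes.
#' @return The raw score S (>= 0).
#' @export
raw_score <- function(profile, positive) {
  N <- attr(profile, "N")
  if (is.null(N)) N <- nrow(profile)
  if (N == 0) return(0)
  r <- profile$rank[profile$gene_id %in% positive]
  sum(N - r + 1)
}

#' Adjust a raw score for negative markers
#'
#' Negative markers are genes expected to be silent in the cell type. A
#' cell is rewarded `weight * N` for each negative marker it does not
#' express (the absence is as informative as a top-rank positive hit) and
#' penalised `N - r + 1` for each negative marker expressed at rank r (the
#' mirror image of a positive contribution). The adjusted score can be
#' negative.
#'
#' @param score Raw score from [raw_score()] on the same profile.
#' @param profile The cell's ranked profile.
#' @param negative Character vector of negative markers (already restricted
#'   to the matrix's gene universe).
#' @param weight Non-negative reward weight, default 1.
#' @return The adjusted score S'.
#' @export
adjust_negative <- function(score, profile, negative, weight = 1) {
  if (length(negative) == 0) return(score)
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  N <- attr(profile, "N")
  if (is.null(N)) N <- nrow(profile)
  expressed <- profile$gene_id %in% negative
  n_expressed <- sum(expressed)
  r <- profile$rank[expressed]
  score + weight * N * (length(negative) - n_expressed) - sum(N - r + 1)
}

#' Normalise a score by the maximum achievable score
#'
#' Raw scores grow with gene-set size, biasing the argmax toward larger
#' sets. The normalised score divides by the best score the set could
#' attain in this cell: all its positives (those present in the gene
#' universe, at most N of them) in the top ranks, and every negative
#' unexpressed. Equals 1 exactly in that best case.
#'
#' @param score Adjusted score S'.
#' @param n_positive Number of the set's positive markers present in the
#'   gene universe.
#' @param n_negative Number of negative markers present in the universe.
#' @param N Number of non-zero genes in the cell.
#' @param weight Negative-marker reward weight used in the adjustment.
#' @return S' / S_max in (-Inf, 1]; `NA` when N = 0 or the set has no
#'   positive marker in the universe (score undefined).
#' @export
normalize_score <- function(score, n_positive, n_negative = 0, N, weight = 1) {
  if (N == 0 || n_positive == 0) return(NA_real_)
  m <- min(n_positive, N)
  s_max <- m * N - m * (m - 1) / 2 + weight * N * n_negative
  score / s_max
}

#' Score every cell against every gene set
#'
#' Transforms a genes-by-cells expression matrix into a gene-sets-by-cells
#' assignment-score matrix. Each cell is scored independently of all
#' others, using only the ranking of its own non-zero genes, so the result
#' is invariant to the expression units and to any per-cell monotone
#' transformation of the data.
#'
#' @param x Genes-by-cells matrix (see [validate_expression()]).
#' @param sets A [gene_sets()] collection.
#' @param normalize Divide each score by the set's maximum achievable score
#'   in that cell (default). Raw scores grow with gene-set size, so with
#'   unequal set sizes the raw argmax drifts toward the largest set;
#'   normalisation removes that bias while leaving the argmax unchanged
#'   whenever all sets have equal size (the Gini index is scale-invariant,
#'   so trimming is likewise unchanged in that case). `FALSE` keeps raw
#'   scores.
#' @param negative_weight Reward weight for unexpressed negative markers.
#' @param quiet Passed to [reconcile_gene_sets()].
#' @return A `score_matrix` object: list with `scores` (M x n matrix, one
#'   row per cell type), `no_marker_expressed` (logical per cell: no set
#'   had any expressed positive marker), `sets` (the reconciled
#'   collection), and `normalized`/`negative_weight` bookkeeping.
#' @export
score_cells <- function(x, sets, normalize = TRUE, negative_weight = 1,
                        quiet = FALSE) {
  x <- validate_expression(x)
  stopifnot(inherits(sets, "gene_set_collection"))
  if (negative_weight < 0) stop("negative_weight must be >= 0", call. = FALSE)
  sets <- reconcile_gene_sets(sets, rownames(x), quiet = quiet)
  M <- length(sets)
  n <- ncol(x)
  gidx <- stats::setNames(seq_len(nrow(x)), rownames(x))

  ## triplet view of the sparse matrix, ranked within each cell;
  ## processed over cell chunks to bound transient memory
  nz_per_cell <- diff(x@p)
  S <- matrix(0, M, n, dimnames = list(names(sets), colnames(x)))
  pos_hits <- matrix(0L, M, n)
  pos_idx <- lapply(sets, function(e) unname(gidx[e$positive]))
  neg_idx <- lapply(sets, function(e) unname(gidx[e$negative]))
  chunk <- 1000L
  for (c0 in seq(1L, n, by = chunk)) {
    c1 <- min(c0 + chunk - 1L, n)
    if (x@p[c1 + 1L] == x@p[c0]) next
    idx <- (x@p[c0] + 1L):(x@p[c1 + 1L])
    nc <- c1 - c0 + 1L
    cell <- rep.int(seq_len(nc), nz_per_cell[c0:c1])
    gene <- x@i[idx] + 1L
    r <- grouped_midrank(-x@x[idx], cell, nc)
    N_of <- nz_per_cell[c0:c1]
    contrib <- N_of[cell] - r + 1
    for (m in seq_len(M)) {
      pos <- pos_idx[[m]]
      neg <- neg_idx[[m]]
      in_pos <- gene %in% pos
      s <- group_sum(contrib[in_pos], cell[in_pos], nc)
      pos_hits[m, c0:c1] <- as.integer(
        group_sum(rep(1, sum(in_pos)), cell[in_pos], nc))
      if (length(neg) > 0) {
        in_neg <- gene %in% neg
        pen <- group_sum(contrib[in_neg], cell[in_neg], nc)
        n_expr_neg <- group_sum(rep(1, sum(in_neg)), cell[in_neg], nc)
        s <- s + negative_weight * N_of * (length(neg) - n_expr_neg) - pen
      }
      if (normalize) {
        mm <- pmin(length(pos), N_of)
        s_max <- mm * N_of - mm * (mm - 1) / 2 +
          negative_weight * N_of * length(neg)
        s <- ifelse(N_of == 0 | length(pos) == 0 | s_max == 0, 0, s / s_max)
      }
      S[m, c0:c1] <- s
    }
  }
  structure(
    list(scores = S,
         no_marker_expressed = colSums(pos_hits > 0) == 0,
         sets = sets,
         normalized = normalize,
         negative_weight = negative_weight),
    class = "score_matrix"
  )
}

## midranks of x within groups (descending handled by caller via sign);
## groups must be sorted ascending, as in a CsparseMatrix triplet.
grouped_midrank <- function(x, group, n_groups) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  o <- order(group, x, method = "radix")
  ## position within group, in sorted order
  sizes <- tabulate(group, nbins = n_groups)
  start <- rep.int(cumsum(c(0L, sizes[-n_groups])), sizes)
  pos <- seq_len(n) - start
  ## midrank of a tie run = first position + (run length - 1) / 2
  gx <- x[o]
  gg <- group[o]
  new_run <- c(TRUE, gx[-1] != gx[-n] | gg[-1] != gg[-n])
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  mid <- rep.int(pos[new_run] + (len - 1) / 2, len)
  r <- numeric(n)
  r[o] <- mid
  r
}

## sum of v by group index (1..n_groups)
group_sum <- function(v, group, n_groups) {
  out <- numeric(n_groups)
  if (length(v) == 0) return(out)
  s <- rowsum(v, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", nrow(x$scores), " cell types x ", ncol(x$scores),
      " cells (", if (x$normalized) "normalized" else "raw", " scores)\n", sep = "")
  invisible(x)
}

#' Tidy a score matrix into a long tibble
#'
#' @param x A `score_matrix` from [score_cells()].
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `cell_type`, `score`.
#' @method tidy score_matrix
#' @export
tidy.score_matrix <- function(x, ...) {
  S <- x$scores
  tibble(
    cell_id = rep(colnames(S), each = nrow(S)),
    cell_type = rep(rownames(S), times = ncol(S)),
    score = as.vector(S)
  )
}

#' Provisional per-cell labels by maximum assignment score
#'
#' Each cell is assigned the cell type whose gene set scored highest. A
#' cell is left `"unclassified"` when the maximum is attained by two or
#' more sets (tied call) or when it expresses no positive marker of any
#' set.
#'
#' @param sm A `score_matrix` from [score_cells()].
#' @return A tibble with columns `cell_id`, `label`, `top_tie`,
#'   `no_marker_expressed`.
#' @export
assign_max <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"))
  S <- sm$scores
  top <- apply(S, 2, max)
  n_at_top <- unname(colSums(S == rep(top, each = nrow(S))))
  label <- rownames(S)[apply(S, 2, which.max)]
  tie <- n_at_top > 1
  label[tie | sm$no_marker_expressed] <- UNCLASSIFIED
  tibble(
    cell_id = colnames(S),
    label = label,
    top_tie = tie,
    no_marker_expressed = sm$no_marker_expressed
  )
}
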