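#' Gini index of a non-negative score vector
#'
#' The mean-absolute-difference Gini index,
#' `G = sum_ij |v_i - v_j| / (2 M^2 mean(v))`, measures how unequally a
#' cell's assignment scores are spread over the M cell types: 0 when all
#' scores are equal (a maximally ambiguous call), `(M-1)/M` when a single
#' score carries everything. Computed with the sorted O(M log M) identity;
#' negative entries (possible after negative-marker adjustment) are floored
#' at 0 first.
#'
#' @param v Numeric vector, length >= 2.
#' @return Gini index in `[0, 1]`, or `NA` when all entries are zero
#'   (undefined; such a cell stays unclassified).
#' @export
gini_index <- function(v) {
  if (length(v) < 2) stop("Gini index needs at least 2 scores", call. = FALSE)
  v[v < 0] <- 0
  mu <- mean(v)
  if (mu == 0) return(NA_real_)
  v <- sort(v)
  M <- length(v)
  sum((2 * seq_len(M) - M - 1) * v) / (M^2 * mu)
}

#' Trim ambiguous calls by the Gini-index outlier rule
#'
#' For every cell the Gini index of its M assignment scores is computed;
#' cells whose index is both a low outlier of the population
#' (`gini < mu - x * sigma`, with mu and sigma the mean and standard
#' deviation of the Gini values across the cells of this annotation run)
#' and below the hard 0.5 cutoff are relabelled `"unclassified"`: their
#' scores are too evenly spread for a trustworthy call. Both inequalities
#' are strict. Trimming only ever removes labels; cells already
#' unclassified (tied or marker-free) are untouched.
#'
#' @param sm A `score_matrix` from [score_cells()].
#' @param labels Provisional labels from [assign_max()] (tibble with
#'   `cell_id`, `label`).
#' @param gini_x Outlier multiplier x in `mu - x * sigma`; default 1.96,
#'   the two-sided 95% normal interval.
#' @return The labels tibble with `label` updated and a `gini` column
#'   appended.
#' @export
trim_labels <- function(sm, labels, gini_x = 1.96) {
  stopifnot(inherits(sm, "score_matrix"))
  if (gini_x <= 0) stop("gini_x must be > 0", call. = FALSE)
  S <- sm$scores
  if (nrow(S) < 2) {
    warning("only one gene set: Gini trimming skipped", call. = FALSE)
    return(dplyr::mutate(labels, gini = NA_real_))
  }
  g <- apply(S, 2, gini_index)
  out <- dplyr::mutate(labels, gini = g)
  defined <- !is.na(g)
  if (sum(defined) >= 2) {
    mu <- mean(g[defined])
    sigma <- stats::sd(g[defined])
    cut <- !is.na(g) & g < mu - gini_x * sigma & g < 0.5
    out$label[cut] <- UNCLASSIFIED
  } else {
    warning("fewer than 2 cells with a defined Gini index: trimming skipped",
            call. = FALSE)
  }
  out$label[is.na(g)] <- UNCLASSIFIED
  out
}
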