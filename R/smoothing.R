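#' Build a k-nearest-neighbour graph in reduced expression space
#'
#' Neighbour relations use the cells' genome-wide expression profiles:
#' counts are library-size scaled (counts per 10,000), `log1p`-transformed,
#' reduced by truncated PCA, and neighbours found by Euclidean distance in
#' the reduced space. This transformation only feeds the optional smoothing
#' step; scoring and trimming never see it. Any externally built graph
#' (e.g. from an existing single-cell pipeline) can be used instead via
#' [read_knn_edges()].
#'
#' @param x Genes-by-cells matrix.
#' @param k Number of neighbours per cell (excluding the cell itself);
#'   must be < number of cells. Default 20.
#' @param n_components Number of principal components, default 30 (capped
#'   at the matrix dimensions).
#' @param seed Integer seed for the randomised truncated decomposition.
#' @return A `knn_graph`: list with `neighbors` (list of integer neighbour
#'   indices per cell), `cell_ids`, `k`.
#' @export
build_knn_graph <- function(x, k = 20, n_components = 30, seed = 1) {
  x <- validate_expression(x)
  n <- ncol(x)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")",
                   call. = FALSE)
  if (n_components < 2) stop("n_components must be >= 2", call. = FALSE)
  libs <- Matrix::colSums(x)
  if (any(libs == 0)) stop("cells with zero total counts cannot be embedded; ",
                           "remove them or supply an external graph", call. = FALSE)
  norm <- x %*% Diagonal(x = 1e4 / libs)
  norm@x <- log1p(norm@x)
  d <- min(n_components, n - 1L, nrow(x) - 1L)
  emb <- withr_seed(seed, {
    if (d >= min(dim(norm)) / 2 || n < 50) {
      ## exact PCA for small problems where the truncated solver is unstable
      p <- stats::prcomp(as.matrix(Matrix::t(norm)), center = TRUE, rank. = d)
      p$x
    } else {
      tn <- Matrix::t(norm)
      f <- irlba::irlba(tn, nv = d, center = Matrix::colMeans(tn), tol = 1e-4)
      f$u %*% diag(f$d, nrow = d)
    }
  })
  rm(norm); gc(FALSE)
  nn <- RANN::nn2(emb, k = k + 1L)
  ## drop self (first neighbour is the cell itself, up to exact ties)
  neighbors <- lapply(seq_len(n), function(j) {
    idx <- nn$nn.idx[j, ]
    idx <- idx[idx != j]
    idx[seq_len(k)]
  })
  structure(list(neighbors = neighbors, cell_ids = colnames(x), k = k),
            class = "knn_graph")
}

## evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read an externally computed neighbour graph from a two-column edge file
#'
#' @param path TSV with two columns of cell identifiers (`from`, `to`); a
#'   header line is detected and skipped. Edges are directed: each row adds
#'   `to` to `from`'s neighbour list.
#' @param cell_ids The cell universe (output column order).
#' @param k_min Declared minimum neighbour count stored as the graph's `k`.
#' @return A `knn_graph`.
#' @export
read_knn_edges <- function(path, cell_ids, k_min = 1L) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(df) > 0 && (!df[1, 1] %in% cell_ids) && (!df[1, 2] %in% cell_ids)) {
    df <- df[-1, , drop = FALSE]  # header line
  }
  from <- match(df[[1]], cell_ids)
  to <- match(df[[2]], cell_ids)
  if (anyNA(from) || anyNA(to)) {
    stop("edge file names cells absent from the matrix", call. = FALSE)
  }
  if (any(from == to)) stop("self-loops are not allowed", call. = FALSE)
  neighbors <- rep(list(integer()), length(cell_ids))
  sp <- split(to, from)
  for (nm in names(sp)) neighbors[[as.integer(nm)]] <- unique(sp[[nm]])
  structure(list(neighbors = neighbors, cell_ids = cell_ids, k = as.integer(k_min)),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat("<knn_graph> ", length(x$cell_ids), " cells, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Single-pass k-nearest-neighbour consensus smoothing of labels
#'
#' Runs exactly once, synchronously: every relabelling decision is taken
#' from the pre-smoothing labels, so the outcome does not depend on the
#' order cells are visited in. A cell with at least `k_min` neighbours is
#' relabelled to its neighbours' most frequent label L iff strictly more
#' than half of *all* its neighbours carry L; otherwise it keeps its label.
#' `"unclassified"` takes part in the consensus like any other label: it
#' can be overwritten by a named consensus and can itself be the consensus.
#'
#' @param labels Character vector of labels, or the tibble produced by the
#'   earlier stages (column `label` used, updated in place).
#' @param graph A `knn_graph`.
#' @param k_min Minimum neighbour count for a cell to be eligible;
#'   defaults to the graph's `k`.
#' @return Same shape as `labels`, smoothed.
#' @export
smooth_labels <- function(labels, graph, k_min = graph$k) {
  stopifnot(inherits(graph, "knn_graph"))
  tib <- is.data.frame(labels)
  lab <- if (tib) labels$label else labels
  if (length(lab) != length(graph$cell_ids)) {
    stop("labels (", length(lab), ") and graph (", length(graph$cell_ids),
         ") cover different numbers of cells", call. = FALSE)
  }
  lev <- unique(lab)
  code <- match(lab, lev)
  new_lab <- lab
  for (j in seq_along(lab)) {
    nbr <- graph$neighbors[[j]]
    deg <- length(nbr)
    if (deg < k_min) next
    counts <- tabulate(code[nbr], nbins = length(lev))
    best <- which.max(counts)
    if (counts[best] > deg / 2) new_lab[j] <- lev[best]
  }
  if (tib) {
    labels$label <- new_lab
    labels
  } else {
    new_lab
  }
}
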