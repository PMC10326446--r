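#' Annotate every cell of an expression matrix from marker gene sets
#'
#' Runs the three sequential per-cell stages: (1) scoring — each cell gets
#' one rank-based assignment score per gene set and is provisionally
#' labelled by the top-scoring cell type; (2) trimming — cells whose scores
#' are spread too evenly (low Gini index, see [trim_labels()]) are
#' relabelled `"unclassified"`; (3) smoothing (optional) — one synchronous
#' pass of k-nearest-neighbour consensus relabelling in reduced expression
#' space. Stages 1-2 are transformation- and cluster-free and operate on
#' each cell independently; only stage 3 looks at other cells.
#'
#' @param x Genes-by-cells matrix of raw or normalised counts (the score is
#'   rank-based, so the units do not matter).
#' @param sets A [gene_sets()] collection (one entry per cell type).
#' @param normalize,negative_weight Scoring options, see [score_cells()].
#' @param trim Apply the Gini trimming stage (default `TRUE`).
#' @param gini_x Outlier multiplier for trimming, see [trim_labels()].
#' @param smooth Apply kNN smoothing (default `TRUE`).
#' @param knn_k,n_components kNN graph construction, see
#'   [build_knn_graph()]. Ignored when `graph` is supplied.
#' @param graph Optional precomputed `knn_graph` covering exactly these
#'   cells.
#' @param seed Integer seed controlling the (only) stochastic component,
#'   the truncated PCA initialisation of the kNN graph.
#' @param quiet Suppress informational messages.
#' @return A `cell_annotation` object; see [tidy.cell_annotation()]. Its
#'   `cells` element is a tibble with per-cell columns `cell_id`, `label`
#'   (final), `gini`, `label_after_scoring`, `label_after_trimming`,
#'   `label_after_smoothing`, `top_tie`, `no_marker_expressed`.
#' @examples
#' x <- Matrix::sparseMatrix(
#'   i = c(1, 2, 3), j = c(1, 2, 3), x = 5,
#'   dims = c(3, 3), dimnames = list(paste0("G", 1:3), paste0("c", 1:3))
#' )
#' ann <- annotate(x, gene_sets(A = "G1", B = "G2"),
#'                 trim = FALSE, smooth = FALSE)
#' tidy(ann)
#' @export
annotate <- function(x, sets,
                     normalize = TRUE, negative_weight = 1,
                     trim = TRUE, gini_x = 1.96,
                     smooth = TRUE, knn_k = 20, n_components = 30,
                     graph = NULL, seed = 1, quiet = FALSE) {
  x <- validate_expression(x)
  sm <- score_cells(x, sets, normalize = normalize,
                    negative_weight = negative_weight, quiet = quiet)
  cells <- assign_max(sm)
  cells$label_after_scoring <- cells$label

  if (trim && nrow(sm$scores) >= 2) {
    cells <- trim_labels(sm, cells, gini_x = gini_x)
  } else {
    if (trim && !quiet) warning("only one gene set: Gini trimming skipped",
                                call. = FALSE)
    cells$gini <- if (nrow(sm$scores) >= 2)
      apply(sm$scores, 2, gini_index) else NA_real_
  }
  cells$label_after_trimming <- cells$label

  if (smooth) {
    if (is.null(graph)) {
      if (knn_k >= ncol(x)) {
        if (!quiet) warning("fewer cells than knn_k + 1: smoothing skipped",
                            call. = FALSE)
        graph <- NULL
      } else {
        graph <- build_knn_graph(x, k = knn_k, n_components = n_components,
                                 seed = seed)
      }
    } else {
      stopifnot(inherits(graph, "knn_graph"))
      if (!identical(graph$cell_ids, colnames(x))) {
        stop("supplied graph does not cover exactly the cells of the matrix",
             call. = FALSE)
      }
    }
    if (!is.null(graph)) cells <- smooth_labels(cells, graph)
  }
  cells$label_after_smoothing <- cells$label

  cells <- dplyr::relocate(cells, "cell_id", "label", "gini",
                           "label_after_scoring", "label_after_trimming",
                           "label_after_smoothing")
  if (!quiet) {
    message(sum(cells$label_after_scoring != UNCLASSIFIED), "/", nrow(cells),
            " cells labelled by scoring; ",
            sum(cells$label_after_trimming == UNCLASSIFIED &
                  cells$label_after_scoring != UNCLASSIFIED), " trimmed; ",
            sum(cells$label_after_smoothing != cells$label_after_trimming),
            " relabelled by smoothing")
  }
  structure(
    list(cells = cells, scores = sm,
         params = list(normalize = normalize, negative_weight = negative_weight,
                       trim = trim, gini_x = gini_x, smooth = smooth,
                       knn_k = knn_k, n_components = n_components, seed = seed)),
    class = "cell_annotation"
  )
}

#' @export
print.cell_annotation <- function(x, ...) {
  tab <- sort(table(x$cells$label), decreasing = TRUE)
  cat("<cell_annotation> ", nrow(x$cells), " cells, ",
      nrow(x$scores$scores), " cell types\n", sep = "")
  print(tab)
  invisible(x)
}

#' Per-cell annotation table
#'
#' @param x A `cell_annotation`.
#' @param ... Unused.
#' @return A tibble, one row per cell, with the final `label`, the `gini`
#'   dispersion of its scores, and the label after each stage.
#' @method tidy cell_annotation
#' @export
tidy.cell_annotation <- function(x, ...) x$cells

#' One-row summary of an annotation run
#'
#' @param x A `cell_annotation`.
#' @param ... Unused.
#' @return A tibble with cell counts per stage outcome.
#' @method glance cell_annotation
#' @export
glance.cell_annotation <- function(x, ...) {
  cc <- x$cells
  tibble(
    n_cells = nrow(cc),
    n_types = nrow(x$scores$scores),
    n_labelled = sum(cc$label != UNCLASSIFIED),
    n_unclassified = sum(cc$label == UNCLASSIFIED),
    n_trimmed = sum(cc$label_after_trimming == UNCLASSIFIED &
                      cc$label_after_scoring != UNCLASSIFIED),
    n_smoothed = sum(cc$label_after_smoothing != cc$label_after_trimming)
  )
}

#' Plot label composition of an annotation
#'
#' @param object A `cell_annotation`.
#' @param ... Unused.
#' @return A ggplot bar chart of cells per final label.
#' @method autoplot cell_annotation
#' @export
autoplot.cell_annotation <- function(object, ...) {
  df <- dplyr::count(object$cells, .data$label)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Re-annotate the cells of one label with a finer gene-set collection
#'
#' Hierarchical sub-annotation: the cells carrying `parent_label` are
#' treated as a stand-alone dataset and re-annotated with `child_sets`
#' (scoring, trimming with its population statistics recomputed on the
#' subset, and smoothing on a kNN graph rebuilt on the subset). The
#' returned object equals `parent` with those cells' final labels replaced
#' by the child labels; all other cells are untouched.
#'
#' @param x The genes-by-cells matrix the parent annotation was made from.
#' @param parent A `cell_annotation` of `x`.
#' @param parent_label The label whose cells are re-annotated.
#' @param child_sets A [gene_sets()] collection for the finer types.
#' @param ... Further arguments passed to [annotate()].
#' @return A `cell_annotation` with updated labels; the child run itself is
#'   kept under `sub_runs[[parent_label]]` of the returned object.
#' @export
sub_annotate <- function(x, parent, parent_label, child_sets, ...) {
  stopifnot(inherits(parent, "cell_annotation"))
  x <- validate_expression(x)
  sel <- parent$cells$label == parent_label
  if (!any(sel)) stop("no cell carries label '", parent_label, "'", call. = FALSE)
  sub <- annotate(x[, parent$cells$cell_id[sel], drop = FALSE], child_sets, ...)
  out <- parent
  out$cells$label[sel] <- sub$cells$label
  out$cells$label_after_smoothing[sel] <- sub$cells$label
  out$sub_runs <- c(parent$sub_runs,
                    stats::setNames(list(sub), parent_label))
  out
}

#' Write an annotation to a TSV file
#'
#' One row per cell in input order: `cell_id`, `label`, `gini`,
#' `label_after_scoring`, `label_after_trimming`, then one score column per
#' cell type. Deterministic: re-running on the same annotation reproduces
#' the file byte for byte.
#'
#' @param ann A `cell_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "cell_annotation"))
  S <- ann$scores$scores
  if (!identical(ann$cells$cell_id, colnames(S))) {
    stop("annotation and score matrix cover different cells", call. = FALSE)
  }
  df <- as.data.frame(ann$cells[, c("cell_id", "label", "gini",
                                    "label_after_scoring",
                                    "label_after_trimming")])
  df <- cbind(df, as.data.frame(Matrix::t(S)))
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Jaccard-index agreement between two annotations
#'
#' For every pair of labels (one from each annotation) the Jaccard index
#' is the size of the intersection over the size of the union of the two
#' cell sets. The diagonal of a self-comparison is all 1.
#'
#' @param labels_a,labels_b Character vectors of labels over the same
#'   cells, in the same order (or `cell_annotation` objects).
#' @return A numeric matrix, labels of `a` in rows, labels of `b` in
#'   columns.
#' @export
jaccard_matrix <- function(labels_a, labels_b) {
  if (inherits(labels_a, "cell_annotation")) labels_a <- labels_a$cells$label
  if (inherits(labels_b, "cell_annotation")) labels_b <- labels_b$cells$label
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors cover different numbers of cells", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  inter <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                  dimnames = dimnames(tab))
  union <- outer(rowSums(inter), colSums(inter), `+`) - inter
  out <- inter / union
  out[union == 0] <- 0
  out
}
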