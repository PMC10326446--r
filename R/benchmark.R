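#' Rotated train/test annotation benchmark on simulated datasets
#'
#' Reproduces the simulation benchmark design: each dataset in turn serves
#' as the training dataset, whose known labels drive Wilcoxon marker
#' inference ([infer_markers()]); the inferred gene sets then annotate
#' every other dataset with the full score-trim-smooth pipeline, and the
#' predicted labels are compared with the simulated truth by pair-based
#' metrics ([pair_metrics()]). With D datasets this yields
#' `D * (D - 1)` trials.
#'
#' @param datasets A list of [simulate_counts()] `sim_truth` objects (or
#'   lists with `counts` and `cell_info`).
#' @param min_fraction,min_logfc,top_n Marker-inference filters, see
#'   [infer_markers()].
#' @param smooth Apply kNN smoothing in the annotation runs (graphs are
#'   built once per dataset and reused across trials).
#' @param seed Seed for the kNN embeddings.
#' @param graphs Optional list of precomputed `knn_graph`s, one per
#'   dataset (e.g. to share graphs across several benchmark calls).
#' @param quiet Suppress per-trial progress messages.
#' @param ... Further arguments passed to [annotate()].
#' @return A tibble with one row per trial: `training`, `testing`, the
#'   pair counts and `sensitivity`, `specificity`, `f1`.
#' @export
run_benchmark <- function(datasets, min_fraction = 0.1, min_logfc = 0.5,
                          top_n = 100, smooth = TRUE, seed = 1,
                          graphs = NULL, quiet = FALSE, ...) {
  stopifnot(length(datasets) >= 2)
  if (is.null(graphs)) graphs <- benchmark_graphs(datasets, smooth, seed)
  D <- length(datasets)
  rows <- list()
  for (tr in seq_len(D)) {
    sets <- infer_markers(datasets[[tr]]$counts, datasets[[tr]]$cell_info$type,
                          min_fraction = min_fraction, min_logfc = min_logfc,
                          top_n = top_n, quiet = TRUE)
    for (te in setdiff(seq_len(D), tr)) {
      ann <- annotate(datasets[[te]]$counts, sets, smooth = smooth,
                      graph = graphs[[te]], seed = seed, quiet = TRUE, ...)
      m <- pair_metrics(datasets[[te]]$cell_info$type, ann$cells$label)
      if (!quiet) {
        message("train ", tr, " -> test ", te,
                sprintf(": SEN %.4f SPC %.4f F1 %.4f",
                        m$sensitivity, m$specificity, m$f1))
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(training = tr, testing = te), m)
      rm(ann); gc(FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Unknown-cell-type discovery benchmark
#'
#' Tests whether cells of types missing from the marker collection are
#' returned as `"unclassified"`. Per repetition a training dataset is
#' picked at random, `n_removed` of its cell types are removed *before*
#' marker inference (so markers are chosen with no knowledge of the
#' removed types), and every other dataset is annotated with the reduced
#' collection. For scoring the truth, cells whose true type was removed
#' are expected `"unclassified"`; pair metrics are computed on all cells
#' with that relabelled truth.
#'
#' @param datasets A list of `sim_truth` objects sharing the same type
#'   universe.
#' @param n_removed Number of types removed per repetition (must leave at
#'   least 2).
#' @param n_reps Number of repetitions, each with its own random choice of
#'   training dataset and removed types.
#' @param min_fraction,min_logfc,top_n Marker filters, see
#'   [infer_markers()].
#' @param smooth Apply kNN smoothing (graphs built once, reused).
#' @param seed Seed for both the random removals and the kNN embeddings.
#' @param graphs Optional list of precomputed `knn_graph`s, one per
#'   dataset.
#' @param quiet Suppress per-trial messages.
#' @param ... Further arguments passed to [annotate()].
#' @return A tibble with one row per (repetition, testing dataset):
#'   `rep`, `training`, `removed` (comma-separated types), `testing`,
#'   pair counts and metrics.
#' @export
run_unknown_type_benchmark <- function(datasets, n_removed = 1, n_reps = 10,
                                       min_fraction = 0.1, min_logfc = 0.5,
                                       top_n = 100, smooth = TRUE, seed = 1,
                                       graphs = NULL, quiet = FALSE, ...) {
  stopifnot(length(datasets) >= 2)
  all_types <- sort(unique(datasets[[1]]$cell_info$type))
  if (n_removed < 1 || n_removed > length(all_types) - 2) {
    stop("n_removed must leave at least 2 types", call. = FALSE)
  }
  if (is.null(graphs)) graphs <- benchmark_graphs(datasets, smooth, seed)
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(n_reps)) {
    tr <- sample(seq_along(datasets), 1)
    removed <- sample(all_types, n_removed)
    keep <- !(datasets[[tr]]$cell_info$type %in% removed)
    sets <- infer_markers(datasets[[tr]]$counts[, keep, drop = FALSE],
                          datasets[[tr]]$cell_info$type[keep],
                          min_fraction = min_fraction, min_logfc = min_logfc,
                          top_n = top_n, quiet = TRUE)
    for (te in setdiff(seq_along(datasets), tr)) {
      truth <- datasets[[te]]$cell_info$type
      truth[truth %in% removed] <- UNCLASSIFIED
      ann <- annotate(datasets[[te]]$counts, sets, smooth = smooth,
                      graph = graphs[[te]], seed = seed, quiet = TRUE, ...)
      m <- pair_metrics(truth, ann$cells$label)
      if (!quiet) {
        message("rep ", rep_i, " (removed ", paste(removed, collapse = ","),
                ") -> test ", te,
                sprintf(": SEN %.4f SPC %.4f F1 %.4f",
                        m$sensitivity, m$specificity, m$f1))
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(rep = rep_i, training = tr,
               removed = paste(removed, collapse = ","), testing = te), m)
      rm(ann); gc(FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

## one kNN graph per dataset, or NULLs when smoothing is off
benchmark_graphs <- function(datasets, smooth, seed) {
  if (!smooth) return(rep(list(NULL), length(datasets)))
  lapply(datasets, function(d) build_knn_graph(d$counts, seed = seed))
}
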