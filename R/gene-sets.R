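#' Build a marker gene-set collection
#'
#' A gene-set collection holds, for each cell type to be detected, the list
#' of positive marker genes (expected to be expressed in that type) and an
#' optional list of negative markers (expected *not* to be expressed).
#' Markers may be shared across cell types; within one cell type a gene
#' cannot be both a positive and a negative marker.
#'
#' @param ... Named arguments, one per cell type. Each value is either a
#'   character vector of positive markers, or a list with elements
#'   `positive` (required, non-empty character vector) and `negative`
#'   (optional character vector).
#' @param .list As an alternative to `...`, a named list in the same format.
#'
#' @return An object of class `gene_set_collection`: a named list whose
#'   entries each carry `positive` and `negative` character vectors, in the
#'   order given.
#'
#' @examples
#' gene_sets(
#'   TNK = c("CD3D", "NKG7"),
#'   CD4T = list(positive = "CD4", negative = c("CD8A", "CD8B"))
#' )
#' @export
gene_sets <- function(..., .list = NULL) {
  entries <- if (is.null(.list)) list(...) else .list
  if (length(entries) == 0) stop("at least one gene set is required", call. = FALSE)
  nms <- names(entries)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every gene set must be named by its cell type", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate cell-type names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  entries <- lapply(nms, function(nm) {
    e <- entries[[nm]]
    if (is.character(e)) e <- list(positive = e, negative = character())
    pos <- unique(as.character(e$positive %||% character()))
    neg <- unique(as.character(e$negative %||% character()))
    if (length(pos) == 0) {
      stop("gene set '", nm, "' has an empty positive marker list", call. = FALSE)
    }
    both <- intersect(pos, neg)
    if (length(both) > 0) {
      stop("gene set '", nm, "' lists ", paste(both, collapse = ", "),
           " as both positive and negative", call. = FALSE)
    }
    list(positive = pos, negative = neg)
  })
  names(entries) <- nms
  structure(entries, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x), " cell types\n", sep = "")
  for (nm in names(x)) {
    cat("  ", nm, ": ", length(x[[nm]]$positive), " positive",
        if (length(x[[nm]]$negative) > 0)
          paste0(", ", length(x[[nm]]$negative), " negative"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a gene-set collection into a long tibble
#'
#' @param x A `gene_set_collection`.
#' @param ... Unused.
#' @return A tibble with columns `cell_type`, `gene`, `direction`
#'   (`"positive"` or `"negative"`).
#' @method tidy gene_set_collection
#' @export
tidy.gene_set_collection <- function(x, ...) {
  purrr::map_dfr(names(x), function(nm) {
    dplyr::bind_rows(
      tibble(cell_type = nm, gene = x[[nm]]$positive, direction = "positive"),
      tibble(cell_type = nm, gene = x[[nm]]$negative, direction = "negative")
    )
  })
}

#' Read marker gene sets from GMT or JSON
#'
#' GMT files (one tab-separated line per set: name, description, genes)
#' carry positive markers only. The JSON dialect maps each cell-type name to
#' an object with `"positive"` and optional `"negative"` arrays (a bare
#' array is read as positive markers), and is the format of choice when
#' negative markers are needed.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"gmt"`, or `"json"`.
#' @return A [gene_sets()] collection in file order.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene-set file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "gmt"
  }
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    entries <- lapply(lines, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) {
        stop("malformed GMT line (need name, description, >=1 gene): ",
             substr(ln, 1, 40), call. = FALSE)
      }
      genes <- f[-(1:2)]
      genes <- genes[nzchar(genes)]
      stats::setNames(list(list(positive = genes, negative = character())), f[1])
    })
    gene_sets(.list = unlist(entries, recursive = FALSE))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    entries <- lapply(obj, function(e) {
      if (is.character(e)) list(positive = e, negative = character())
      else list(positive = as.character(e$positive %||% character()),
                negative = as.character(e$negative %||% character()))
    })
    gene_sets(.list = entries)
  }
}

#' Drop markers absent from an expression matrix's gene universe
#'
#' Marker genes are matched to matrix rownames as exact case-sensitive
#' strings; markers not present are removed from each set with a warning.
#' A set losing all its positive markers is kept (it can then never win the
#' argmax) so that over-specified collections remain valid inputs.
#'
#' @param sets A `gene_set_collection`.
#' @param gene_ids Character vector of gene identifiers (the matrix rows).
#' @param quiet Suppress the warning listing dropped markers.
#' @return The reconciled `gene_set_collection`.
#' @export
reconcile_gene_sets <- function(sets, gene_ids, quiet = FALSE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  dropped <- character()
  out <- lapply(sets, function(e) {
    miss <- setdiff(c(e$positive, e$negative), gene_ids)
    dropped <<- union(dropped, miss)
    list(positive = intersect(e$positive, gene_ids),
         negative = intersect(e$negative, gene_ids))
  })
  if (length(dropped) > 0 && !quiet) {
    warning(length(dropped), " marker gene(s) absent from the matrix were dropped: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...", call. = FALSE)
  }
  structure(out, class = "gene_set_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
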