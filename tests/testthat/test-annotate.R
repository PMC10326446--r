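test_that("separable two-type toy is fully and correctly labelled", {
  x <- separable_matrix(10)
  ann <- annotate(x, separable_sets(), smooth = FALSE, quiet = TRUE)
  td <- tidy(ann)
  expect_equal(td$label, rep(c("A", "B"), each = 10))
  expect_equal(sum(td$label == "unclassified"), 0)
  g <- glance(ann)
  expect_equal(g$n_cells, 20L)
  expect_equal(g$n_unclassified, 0L)
})

test_that("a cell expressing no markers ends unclassified through every stage", {
  x <- separable_matrix(10)
  x[, 5] <- 0
  x[25, 5] <- 3  # only a background gene
  x <- validate_expression(x)
  ann <- annotate(x, separable_sets(), smooth = FALSE, quiet = TRUE)
  td <- tidy(ann)
  expect_equal(td$label_after_scoring[5], "unclassified")
  expect_equal(td$label[5], "unclassified")
  expect_true(td$no_marker_expressed[5])
})

test_that("annotation is deterministic given a seed", {
  sim <- simulate_counts(200, 3, n_genes = 300, seed = 8, lib_loc = 7)
  sets <- gene_sets(.list = lapply(split(
    rownames(sim$counts)[apply(sim$de_factors, 2, which.max)],
    colnames(sim$de_factors)), identity))
  a1 <- annotate(sim$counts, sets, knn_k = 10, seed = 99, quiet = TRUE)
  a2 <- annotate(sim$counts, sets, knn_k = 10, seed = 99, quiet = TRUE)
  expect_identical(tidy(a1), tidy(a2))
  expect_identical(a1$scores$scores, a2$scores$scores)
})

test_that("final labels ignore per-cell monotone rescaling when smoothing is off", {
  x <- separable_matrix(8, seed = 4)
  ann <- annotate(x, separable_sets(), smooth = FALSE, quiet = TRUE)
  x2 <- x
  for (j in seq_len(ncol(x2))) x2[, j] <- x2[, j] * (10 ^ (j %% 3))
  x2 <- validate_expression(x2)
  ann2 <- annotate(x2, separable_sets(), smooth = FALSE, quiet = TRUE)
  expect_identical(tidy(ann)$label, tidy(ann2)$label)
})

test_that("sub-annotation only touches the parent label's cells", {
  ## build 3 groups: A1, A2 (subtypes of A) and B
  set.seed(6)
  n <- 30
  m <- matrix(0, 40, 3 * n)
  m[31:40, ] <- rpois(10 * 3 * n, 2) + 1          # background
  m[1:5, 1:(2 * n)] <- rpois(5 * 2 * n, 9) + 1     # A shared markers
  m[6:10, 1:n] <- rpois(5 * n, 9) + 1              # A1
  m[11:15, n + 1:n] <- rpois(5 * n, 9) + 1         # A2
  m[16:25, 2 * n + 1:n] <- rpois(10 * n, 9) + 1    # B
  dimnames(m) <- list(sprintf("G%03d", 1:40), sprintf("c%03d", 1:(3 * n)))
  x <- validate_expression(m)

  parent_sets <- gene_sets(A = sprintf("G%03d", 1:5), B = sprintf("G%03d", 16:25))
  parent <- annotate(x, parent_sets, smooth = FALSE, quiet = TRUE)
  expect_equal(tidy(parent)$label, rep(c("A", "B"), times = c(2 * n, n)))

  child_sets <- gene_sets(A1 = sprintf("G%03d", 6:10),
                          A2 = sprintf("G%03d", 11:15))
  sub <- sub_annotate(x, parent, "A", child_sets, smooth = FALSE, quiet = TRUE)
  lab <- tidy(sub)$label
  expect_equal(lab[2 * n + 1:n], rep("B", n))          # untouched
  expect_equal(lab[1:n], rep("A1", n))
  expect_equal(lab[n + 1:n], rep("A2", n))
  expect_named(sub$sub_runs, "A")

  expect_error(sub_annotate(x, parent, "Zed", child_sets), "no cell carries")
})

test_that("a single-cell subset still scores but skips trimming with a warning", {
  x <- separable_matrix(6)
  parent <- annotate(x, separable_sets(), smooth = FALSE, quiet = TRUE)
  one <- parent
  one$cells$label[1] <- "Solo"
  expect_warning(
    sub <- sub_annotate(x, one, "Solo",
                        gene_sets(S1 = "G001", S2 = "G002"),
                        smooth = FALSE),
    "trimming skipped|fewer than 2")
  expect_true(tidy(sub)$label[1] %in% c("S1", "S2", "unclassified"))
})

test_that("two-level hierarchical drill-down mirrors broad-to-fine annotation", {
  ## TNK -> {T, NK}, then T -> {CD4 T, CD8 T}
  set.seed(14)
  n <- 20
  m <- matrix(0, 50, 4 * n)
  m[41:50, ] <- rpois(10 * 4 * n, 2) + 1
  m[1:4, 1:(3 * n)] <- rpois(4 * 3 * n, 9) + 1        # TNK shared (T + NK)
  m[5:8, 1:(2 * n)] <- rpois(4 * 2 * n, 9) + 1        # T shared
  m[9:12, 1:n] <- rpois(4 * n, 9) + 1                 # CD4
  m[13:16, n + 1:n] <- rpois(4 * n, 9) + 1            # CD8
  m[17:20, 2 * n + 1:n] <- rpois(4 * n, 9) + 1        # NK-specific
  m[21:30, 3 * n + 1:n] <- rpois(10 * n, 9) + 1       # MPh
  dimnames(m) <- list(sprintf("G%03d", 1:50), sprintf("c%03d", 1:(4 * n)))
  x <- validate_expression(m)

  lvl1 <- annotate(x, gene_sets(TNK = sprintf("G%03d", 1:4),
                                MPh = sprintf("G%03d", 21:30)),
                   smooth = FALSE, quiet = TRUE)
  lvl2 <- sub_annotate(x, lvl1, "TNK",
                       gene_sets(T = sprintf("G%03d", 5:8),
                                 NK = sprintf("G%03d", 17:20)),
                       smooth = FALSE, quiet = TRUE)
  lvl3 <- sub_annotate(x, lvl2, "T",
                       gene_sets(CD4T = sprintf("G%03d", 9:12),
                                 CD8T = sprintf("G%03d", 13:16)),
                       smooth = FALSE, quiet = TRUE)
  lab <- tidy(lvl3)$label
  expect_equal(lab, rep(c("CD4T", "CD8T", "NK", "MPh"), each = n))
})

test_that("negative markers separate types sharing positive markers", {
  ## two types share marker G001; G002 distinguishes: present in B only.
  set.seed(19)
  n <- 15
  m <- matrix(0, 10, 2 * n)
  m[10, ] <- rpois(2 * n, 3) + 1
  m[1, ] <- rpois(2 * n, 8) + 1              # shared positive
  m[2, n + 1:n] <- rpois(n, 8) + 1           # B-specific
  dimnames(m) <- list(sprintf("G%03d", 1:10), sprintf("c%03d", 1:(2 * n)))
  x <- validate_expression(m)
  sets <- gene_sets(
    A = list(positive = "G001", negative = "G002"),
    B = list(positive = c("G001", "G002"))
  )
  ann <- annotate(x, sets, smooth = FALSE, trim = FALSE, quiet = TRUE)
  expect_equal(tidy(ann)$label, rep(c("A", "B"), each = n))
})

test_that("autoplot returns a ggplot object", {
  ann <- annotate(separable_matrix(), separable_sets(), smooth = FALSE,
                  quiet = TRUE)
  expect_s3_class(autoplot(ann), "ggplot")
})
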