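test_that("ranking keeps only non-zero genes, high to low, with midranks for ties", {
  p <- rank_nonzero(c(geneA = 7, geneB = 0, geneC = 3, geneD = 1))
  expect_equal(attr(p, "N"), 3)
  expect_equal(p$gene_id, c("geneA", "geneC", "geneD"))
  expect_equal(p$rank, c(1, 2, 3))

  p2 <- rank_nonzero(c(A = 5, B = 5, C = 2))
  expect_equal(p2$rank[p2$gene_id %in% c("A", "B")], c(1.5, 1.5))
  expect_equal(p2$rank[p2$gene_id == "C"], 3)

  p0 <- rank_nonzero(c(A = 0, B = 0))
  expect_equal(attr(p0, "N"), 0)
  expect_equal(nrow(p0), 0)

  ## midranks always sum to N(N+1)/2
  set.seed(1)
  for (i in 1:20) {
    v <- sample(0:5, 30, replace = TRUE)
    names(v) <- paste0("g", seq_along(v))
    p <- rank_nonzero(v)
    N <- attr(p, "N")
    expect_equal(sum(p$rank), N * (N + 1) / 2)
  }
})

test_that("closed-form score matches the literal nested double sum", {
  ## worked micro-example: N = 5, markers at ranks 1 and 3
  expr <- c(m1 = 10, x1 = 8, m2 = 6, x2 = 4, x3 = 2)
  p <- rank_nonzero(expr)
  expect_identical(raw_score(p, c("m1", "m2")), 8)
  expect_identical(double_sum_score(p$gene_id, c("m1", "m2")), 8L)

  ## no marker expressed
  expect_identical(raw_score(p, c("nope")), 0)
  ## all genes markers: N(N+1)/2
  expr4 <- c(a = 4, b = 3, c = 2, d = 1)
  expect_identical(raw_score(rank_nonzero(expr4), names(expr4)), 10)

  ## fuzz: tie-free profiles up to 200 genes
  set.seed(42)
  for (i in 1:1000) {
    n_genes <- sample(2:200, 1)
    expr <- sample(seq_len(5 * n_genes), n_genes)  # distinct -> tie-free
    names(expr) <- paste0("g", seq_len(n_genes))
    markers <- sample(names(expr), sample(seq_len(n_genes), 1))
    p <- rank_nonzero(expr)
    expect_identical(raw_score(p, markers),
                     as.numeric(double_sum_score(p$gene_id, markers)))
  }
})

test_that("score is invariant under monotone transforms and never decreases on promotion", {
  set.seed(7)
  for (i in 1:50) {
    expr <- c(stats::rpois(40, 3))
    names(expr) <- paste0("g", seq_along(expr))
    markers <- sample(names(expr), 8)
    s0 <- raw_score(rank_nonzero(expr), markers)
    ## strictly monotone transforms preserve all non-zero ranks
    expect_equal(raw_score(rank_nonzero(expr * 10), markers), s0)
    expect_equal(raw_score(rank_nonzero(sqrt(expr)), markers), s0)
    expect_equal(raw_score(rank_nonzero(expr^3), markers), s0)
  }

  ## promoting an expressed marker to a strictly better rank never lowers S
  expr <- c(m = 2, a = 9, b = 7, c = 5, d = 3)
  s_before <- raw_score(rank_nonzero(expr), "m")
  expr["m"] <- 8  # move up
  expect_gte(raw_score(rank_nonzero(expr), "m"), s_before)
})

test_that("negative markers reward absence and penalise expression", {
  expr <- c(m = 10, a = 8, b = 6, c = 4, d = 2)  # N = 5
  p <- rank_nonzero(expr)
  s <- raw_score(p, "m")
  expect_equal(adjust_negative(s, p, character(), 1), s)
  ## one unexpressed negative, w = 1: + N
  expect_equal(adjust_negative(s, p, "absent", 1), s + 5)
  ## negative expressed at rank 1: - (N - 1 + 1)
  expect_equal(adjust_negative(s, p, "m", 1) - s, -5 + 0)  # m IS rank 1: -5, no reward
  ## weight scales the reward
  expect_equal(adjust_negative(s, p, "absent", 2), s + 10)
})

test_that("normalisation maps the best case to 1 and bounds all scores", {
  ## markers at top ranks, no negatives -> 1
  expr <- c(m1 = 9, m2 = 8, a = 2, b = 1)
  p <- rank_nonzero(expr)
  expect_equal(normalize_score(raw_score(p, c("m1", "m2")), 2, 0, 4), 1)
  ## worked example: N = 5, |G| = 2, ranks 1 and 3 -> 8/9
  expect_equal(normalize_score(8, 2, 0, 5), 8 / 9)
  ## undefined cases
  expect_true(is.na(normalize_score(0, 0, 0, 5)))
  expect_true(is.na(normalize_score(0, 3, 0, 0)))

  set.seed(11)
  for (i in 1:100) {
    expr <- stats::rpois(30, 2)
    names(expr) <- paste0("g", seq_along(expr))
    p <- rank_nonzero(expr)
    N <- attr(p, "N")
    if (N == 0) next
    markers <- sample(names(expr), 5)
    n_univ <- 5
    s <- normalize_score(raw_score(p, markers), n_univ, 0, N)
    expect_lte(s, 1)
    expect_gte(s, 0)
    expect_lte(raw_score(p, markers), N * (N + 1) / 2)
  }
})

test_that("the matrix scorer agrees with the per-cell reference path", {
  x <- toy_matrix(50, 25, seed = 3)
  sets <- gene_sets(
    A = sprintf("G%03d", 1:6),
    B = list(positive = sprintf("G%03d", 7:18),
             negative = sprintf("G%03d", 19:21))
  )
  for (nrm in c(FALSE, TRUE)) {
    sm <- score_cells(x, sets, normalize = nrm)
    for (j in seq_len(ncol(x))) {
      p <- rank_nonzero(x[, j])
      N <- attr(p, "N")
      sA <- raw_score(p, sets$A$positive)
      sB <- adjust_negative(raw_score(p, sets$B$positive), p,
                            sets$B$negative, 1)
      if (nrm) {
        sA <- normalize_score(sA, 6, 0, N)
        sB <- normalize_score(sB, 12, 3, N)
        sA <- ifelse(is.na(sA), 0, sA)
        sB <- ifelse(is.na(sB), 0, sB)
      }
      expect_equal(sm$scores["A", j], sA, tolerance = 1e-12)
      expect_equal(sm$scores["B", j], sB, tolerance = 1e-12)
    }
  }
})

test_that("scoring each cell is independent of the other cells", {
  x <- toy_matrix(40, 15, seed = 5)
  sets <- gene_sets(A = sprintf("G%03d", 1:8), B = sprintf("G%03d", 9:16))
  sm <- score_cells(x, sets)
  ## permuting cells permutes score columns identically
  perm <- sample(ncol(x))
  smp <- score_cells(x[, perm], sets)
  expect_identical(smp$scores, sm$scores[, perm])
  ## dropping cells leaves the rest bit-identical
  smd <- score_cells(x[, 1:5], sets)
  expect_identical(smd$scores, sm$scores[, 1:5])
  ## rescaling one cell's expression leaves its scores unchanged
  x2 <- x
  x2[, 3] <- x2[, 3] * 10
  expect_identical(score_cells(x2, sets)$scores, sm$scores)
})

test_that("argmax labels, ties and marker-free cells behave as specified", {
  sm <- structure(list(
    scores = matrix(c(40, 12, 7, 7, 0, 0), nrow = 2,
                    dimnames = list(c("TNK", "MPh"), c("c1", "c2", "c3"))),
    no_marker_expressed = c(FALSE, FALSE, TRUE),
    sets = NULL, normalized = FALSE, negative_weight = 1
  ), class = "score_matrix")
  lab <- assign_max(sm)
  expect_equal(lab$label, c("TNK", "unclassified", "unclassified"))
  expect_equal(lab$top_tie, c(FALSE, TRUE, TRUE))
  expect_equal(lab$no_marker_expressed, c(FALSE, FALSE, TRUE))
})

test_that("an unmatched extra gene set leaves other scores bit-identical", {
  x <- toy_matrix(60, 20, seed = 9)
  sets <- gene_sets(A = sprintf("G%03d", 1:10), B = sprintf("G%03d", 11:20))
  over <- gene_sets(A = sprintf("G%03d", 1:10), B = sprintf("G%03d", 11:20),
                    Ghost = c("NOT_A_GENE_1", "NOT_A_GENE_2"))
  s1 <- score_cells(x, sets, quiet = TRUE)
  s2 <- score_cells(x, over, quiet = TRUE)
  expect_identical(s2$scores[c("A", "B"), ], s1$scores)
  expect_true(all(s2$scores["Ghost", ] == 0))
})

test_that("tidy() of a score matrix is a long cell x type tibble", {
  x <- toy_matrix(20, 4, seed = 2)
  sm <- score_cells(x, gene_sets(A = sprintf("G%03d", 1:5),
                                 B = sprintf("G%03d", 6:10)))
  td <- tidy(sm)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)
  expect_equal(td$score[td$cell_id == "c002" & td$cell_type == "A"],
               sm$scores["A", "c002"])
})
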