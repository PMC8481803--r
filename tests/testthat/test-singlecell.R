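# Single-cell workflow: QC, normalization, top-N, per-cell ORA, group
# testing, pseudo-bulk.

sc_counts <- function(x) {
  expr_mat(x, mode = "counts")
}

test_that("QC keeps cells by detected genes and drops empty genes", {
  x <- cbind(
    good1 = c(5, 3, 2, 0),
    good2 = c(1, 1, 1, 1),
    empty = c(0, 0, 0, 0),
    huge = c(100, 100, 100, 100)
  )
  rownames(x) <- paste0("g", 1:4)
  m <- sc_counts(x)
  f <- qc_filter(m, min_genes = 2, max_genes = 10, max_total = 50)
  expect_equal(colnames(expr_values(f)), c("good1", "good2"))
  log <- attr(f, "qc_log")
  expect_equal(log$removed[log$criterion == "too_few_genes"], 1)
  expect_equal(log$removed[log$criterion == "total_counts"], 1)
  # all cells within bounds -> identity on cells
  f2 <- qc_filter(m, min_genes = 0, max_genes = 100, max_total = Inf)
  expect_equal(ncol(expr_values(f2)), 4)
  expect_error(qc_filter(m, min_genes = 100), "No cell")
  expect_error(qc_filter(normalize_cells(f), min_genes = 1), "counts")
})

test_that("planted failing cells are exactly the QC casualties", {
  fx <- make_single_cell(17,
    n_genes = 400,
    cells_per_group = c(ARDS = 30, NonVent = 30, Healthy = 30),
    n_program = 20
  )
  f <- qc_filter(fx$matrix, min_genes = 100)
  removed <- setdiff(colnames(expr_values(fx$matrix)), colnames(expr_values(f)))
  expect_setequal(removed, fx$truth$failing_cells)
})

test_that("normalization scales every cell to the target total", {
  withr::with_seed(3, {
    x <- matrix(stats::rpois(200, 5), nrow = 20)
    rownames(x) <- paste0("g", 1:20)
    colnames(x) <- paste0("c", 1:10)
    m <- sc_counts(x)
    norm <- normalize_cells(m)
    pre_log <- expm1(expr_values(norm))
    expect_equal(
      unname(colSums(pre_log)), rep(1e4, 10),
      tolerance = 1e-6
    )
    # doubling a cell's counts leaves its normalized column unchanged
    x2 <- x
    x2[, 1] <- x[, 1] * 2
    norm2 <- normalize_cells(sc_counts(x2))
    expect_equal(
      expr_values(norm2)[, 1], expr_values(norm)[, 1],
      tolerance = 1e-12
    )
  })
  # single-gene cell: scaled value 1e4, stored log(10001)
  x1 <- matrix(7, 1, 1, dimnames = list("g1", "c1"))
  expect_equal(
    as.numeric(expr_values(normalize_cells(sc_counts(x1)))), log(10001)
  )
  x0 <- matrix(0, 1, 1, dimnames = list("g1", "c1"))
  expect_error(normalize_cells(sc_counts(x0)), "Zero-total")
})

test_that("top-N selection respects ties and short cells", {
  x <- cbind(
    c1 = c(3, 2, 2, 1),
    c2 = c(1, 0, 0, 0)
  )
  rownames(x) <- c("gd", "gb", "ga", "gz")
  m <- expr_mat(x, mode = "normalized")
  top <- top_n_genes(m, 2)
  # boundary tie between GA and GB at value 2 -> lexicographic winner GA
  expect_equal(top$genes[[1]], c("GD", "GA"))
  expect_false(top$truncated[1])
  # cell with fewer detected genes than n uses all, flagged
  expect_equal(top$genes[[2]], "GD")
  expect_true(top$truncated[2])
  # n = 1 picks the argmax
  expect_equal(top_n_genes(m, 1)$genes[[1]], "GD")
})

test_that("per-cell activity is a -log10 hypergeometric tail", {
  fx <- make_single_cell(23,
    n_genes = 300,
    cells_per_group = c(ARDS = 25, NonVent = 25, Healthy = 25),
    n_program = 20, n_fail_per_group = 0
  )
  f <- qc_filter(fx$matrix, min_genes = 50)
  norm <- normalize_cells(f)
  top <- top_n_genes(norm, 60)
  gs <- make_genesets(
    23, expr_genes(f), intersect(fx$truth$program_genes, expr_genes(f)),
    n_decoys = 10
  )
  act <- per_cell_ora(top, gs$sets, expr_genes(f), cell_data = f$col_data)
  expect_true(all(act$activity >= 0))
  # spot check one cell/category against the single-test function
  cell <- 5
  cat_name <- colnames(act$p)[3]
  members <- gs$sets$genes[[which(gs$sets$set == cat_name)]]
  direct <- ora(
    top$genes[[cell]], expr_genes(f), members,
    sided = "enrichment"
  )$p_raw
  expect_equal(unname(act$p[cell, cat_name]), direct, tolerance = 1e-12)
  # program cells show higher planted-category activity than background
  planted_col <- act$activity[, gs$truth$planted_set]
  grp <- f$col_data$group
  expect_gt(
    stats::median(planted_col[grp == "ARDS"]),
    stats::median(planted_col[grp != "ARDS"])
  )
  # the tested category list is identical for every cell (matrix shape)
  expect_equal(nrow(act$activity), nrow(top))
})

test_that("group testing finds the planted program only in its group", {
  fx <- make_single_cell(29, n_genes = 600)
  f <- qc_filter(fx$matrix)
  norm <- normalize_cells(f)
  top <- top_n_genes(norm, 150)
  gs <- make_genesets(
    29, expr_genes(f), intersect(fx$truth$program_genes, expr_genes(f)),
    n_decoys = 15
  )
  act <- per_cell_ora(top, gs$sets, expr_genes(f), cell_data = f$col_data)
  res <- group_activity_test(act)
  planted <- res[res$category == gs$truth$planted_set, ]
  sig_more <- planted$group[
    planted$p_adj <= 0.05 & planted$direction == "more_active"
  ]
  expect_equal(sig_more, fx$truth$program_group)
  # negating activities flips every direction
  act_neg <- act
  act_neg$activity <- -act$activity
  res_neg <- group_activity_test(act_neg)
  merged <- dplyr::inner_join(
    res, res_neg,
    by = c("category", "group"), suffix = c("", "_neg")
  )
  nonzero <- abs(merged$statistic) > 1e-9
  expect_true(all(
    merged$direction[nonzero] != merged$direction_neg[nonzero]
  ))
})

test_that("identical groups produce no significant activity difference", {
  act_mat <- matrix(rep(c(1, 2, 3, 4, 5), 2), ncol = 1,
    dimnames = list(paste0("c", 1:10), "cat1")
  )
  a <- structure(
    list(
      activity = act_mat, p = 10^-act_mat,
      cell_data = tibble::tibble(
        id = paste0("c", 1:10), group = rep(c("x", "y"), each = 5)
      ),
      skipped = tibble::tibble()
    ),
    class = "tk_cell_activity"
  )
  res <- group_activity_test(a)
  expect_equal(res$p_raw, c(1, 1))
})

test_that("pseudo-bulk sums cells per sample and conserves counts", {
  x <- cbind(
    c1 = c(1, 2, 3), c2 = c(4, 5, 6), c3 = c(7, 8, 9)
  )
  rownames(x) <- paste0("g", 1:3)
  m <- expr_mat(x,
    col_data = tibble::tibble(
      id = colnames(x), sample = c("s1", "s1", "s2")
    ),
    mode = "counts"
  )
  pb <- pseudo_bulk(m)
  expect_equal(unname(expr_values(pb)[, "s1"]), c(5, 7, 9))
  expect_equal(unname(expr_values(pb)[, "s2"]), c(7, 8, 9))
  expect_identical(sum(expr_values(pb)), sum(x))
  # one cell per sample -> identity on values
  m1 <- expr_mat(x,
    col_data = tibble::tibble(id = colnames(x), sample = colnames(x)),
    mode = "counts"
  )
  expect_equal(unname(expr_values(pseudo_bulk(m1))), unname(x))
  # unlabeled cell rejected
  m_na <- expr_mat(x,
    col_data = tibble::tibble(
      id = colnames(x), sample = c("s1", NA, "s2")
    ),
    mode = "counts"
  )
  expect_error(pseudo_bulk(m_na), "Unlabeled")
})
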