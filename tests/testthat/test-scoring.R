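# Per-gene differential scoring and filter procedures.

test_that("log fold change matches exact arithmetic and is antisymmetric", {
  fx <- tiny_bulk()
  s <- score_log_fold_change(fx$m, fx$groups, pseudocount = 0)
  sl <- tibble::deframe(s)
  expect_equal(unname(sl["UP"]), log2(9 / 3)) # means 9 vs 3
  expect_equal(unname(sl["FLAT"]), 0) # equal means -> 0
  # group swap negates every score
  s_swap <- score_log_fold_change(fx$m, fx$groups,
    pseudocount = 0, group_a = "B", group_b = "A"
  )
  expect_equal(
    tibble::deframe(s_swap)[names(sl)], -sl,
    tolerance = 1e-12
  )
  # meanA = 8, meanB = 2, pseudocount 0 -> exactly 2
  x <- matrix(c(8, 2), 1, dimnames = list("g", c("a1", "b1")))
  m1 <- expr_mat(x, mode = "normalized")
  g1 <- tibble::tibble(id = c("a1", "b1"), group = c("A", "B"))
  expect_equal(score_log_fold_change(m1, g1, pseudocount = 0)$score, 2)
  # zero mean with zero pseudocount is an error naming the gene
  x0 <- matrix(c(0, 2), 1, dimnames = list("gz", c("a1", "b1")))
  expect_error(
    score_log_fold_change(expr_mat(x0, mode = "counts"), g1, pseudocount = 0),
    "GZ"
  )
})

test_that("Welch t matches t.test and handles degenerate variance", {
  x <- rbind(
    G1 = c(1, 2, 3, 4, 5, 6),
    G2 = c(3, 3, 3, 3, 3, 3)
  )
  colnames(x) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m <- expr_mat(x, mode = "normalized")
  g <- tibble::tibble(id = colnames(x), group = rep(c("A", "B"), each = 3))
  expect_warning(s <- score_t_test(m, g), "zero variance")
  sl <- tibble::deframe(s)
  # independent oracle: Welch formula via stats::t.test
  oracle <- stats::t.test(c(1, 2, 3), c(4, 5, 6))$statistic
  expect_equal(unname(sl["G1"]), unname(oracle), tolerance = 1e-12)
  expect_equal(unname(sl["G1"]), -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(sl["G2"]), 0)
  expect_equal(attr(s, "degenerate"), "G2")
  # scale invariance
  m2 <- expr_mat(x * 10, mode = "normalized")
  expect_warning(s2 <- score_t_test(m2, g))
  expect_equal(tibble::deframe(s2)[names(sl)], sl, tolerance = 1e-12)
  # group of size < 2 rejected
  g_bad <- tibble::tibble(
    id = colnames(x), group = c("A", rep("B", 5))
  )
  expect_error(score_t_test(m, g_bad), "at least 2")
})

test_that("Wilcoxon z matches the rank-sum formula and enumeration", {
  x <- matrix(c(10, 9, 1, 2), 1,
    dimnames = list("g", c("a1", "a2", "b1", "b2"))
  )
  m <- expr_mat(x, mode = "normalized")
  g <- tibble::tibble(
    id = colnames(x), group = rep(c("A", "B"), each = 2)
  )
  z <- score_wilcoxon(m, g)$score
  # W = 7, mu = 5, sigma^2 = 2*2*5/12
  expect_equal(z, (7 - 5) / sqrt(5 / 3), tolerance = 1e-12)
  # antisymmetry under group swap
  z_swap <- score_wilcoxon(m, g, group_a = "B", group_b = "A")$score
  expect_equal(z_swap, -z, tolerance = 1e-12)
  # constant gene scores 0
  xc <- matrix(5, 1, 4, dimnames = dimnames(x))
  expect_equal(
    score_wilcoxon(expr_mat(xc, mode = "normalized"), g)$score, 0
  )
})

test_that("normal approximation tracks exhaustive enumeration at n=4+4", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      vals <- round(stats::rnorm(8), 2)
      a <- vals[1:4]
      b <- vals[5:8]
      x <- matrix(vals, 1,
        dimnames = list("g", paste0("s", 1:8))
      )
      g <- tibble::tibble(
        id = paste0("s", 1:8), group = rep(c("A", "B"), each = 4)
      )
      z <- score_wilcoxon(expr_mat(x, mode = "normalized"), g)$score
      # exact null: all C(8,4) assignments of the observed values
      w_obs <- sum(rank(vals)[1:4])
      combos <- utils::combn(8, 4)
      w_null <- apply(combos, 2, function(i) sum(rank(vals)[i]))
      p_exact <- mean(w_null >= w_obs)
      p_norm <- stats::pnorm(z, lower.tail = FALSE)
      expect_lt(abs(p_norm - p_exact), 0.15)
    }
  })
})

test_that("absolute transform re-sorts, is idempotent, keeps zeros", {
  s <- tibble::tibble(gene = c("A", "B"), score = c(-3, 2))
  a <- transform_abs(s)
  expect_equal(a$gene, c("A", "B"))
  expect_equal(a$score, c(3, 2))
  expect_equal(transform_abs(a), a)
  z <- tibble::tibble(gene = c("A", "B"), score = c(0, 0))
  expect_equal(transform_abs(z)$score, c(0, 0))
})

test_that("deregulated-gene selection rules follow their definitions", {
  s <- tibble::tibble(gene = paste0("G", 1:5), score = c(5, 4, 3, 2, 1))
  expect_equal(
    select_deregulated(s, top_k = 5), sort(paste0("G", 1:5))
  )
  expect_equal(select_deregulated(s, abs_threshold = 0), sort(s$gene))
  # upper_lower_percent(20) on 5 genes -> 1 per tail
  expect_equal(
    select_deregulated(s, upper_lower_percent = 20), c("G1", "G5")
  )
  expect_equal(select_deregulated(s, top_k = 2), c("G1", "G2"))
  expect_error(select_deregulated(s, top_k = 6), "\\[1, 5\\]")
  expect_error(select_deregulated(s), "exactly one")
  # tie at the boundary broken by gene token
  st <- tibble::tibble(gene = c("b", "a", "c"), score = c(1, 1, 0))
  expect_equal(select_deregulated(st, top_k = 1), "A")
})

test_that("scoring is invariant under gene-row permutation", {
  fx <- tiny_bulk()
  perm <- expr_mat(
    expr_values(fx$m)[c(3, 1, 4, 2), ], mode = "normalized"
  )
  for (f in list(score_log_fold_change, score_wilcoxon)) {
    expect_equal(f(fx$m, fx$groups), f(perm, fx$groups))
  }
})
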