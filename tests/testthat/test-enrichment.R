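# Set-level statistics: ORA, running-sum ES, FCS family, adjustment,
# and the enrichment driver.

test_that("hypergeometric ORA matches closed form and enumeration", {
  ref <- paste0("g", 1:10)
  # N=10, K=4, n=5, k=4 -> C(4,4)C(6,1)/C(10,5) = 6/252
  rec <- ora(ref[1:5], ref, ref[1:4], sided = "enrichment")
  expect_equal(rec$p_raw, 6 / 252, tolerance = 1e-14)
  expect_equal(rec$hits, 4L)
  expect_equal(rec$direction, "enriched")
  expect_equal(rec$hit_genes[[1]], c("G1", "G2", "G3", "G4"))
  # against the exhaustive enumeration oracle
  oracle <- ora_enum_oracle(10, 5, 5, 4)
  ref2 <- paste0("g", 1:10)
  cat2 <- paste0("g", 1:5)
  enr <- ora(ref2[c(1:4, 6)], ref2, cat2, sided = "enrichment")$p_raw
  dep <- ora(ref2[c(1:4, 6)], ref2, cat2, sided = "depletion")$p_raw
  expect_equal(enr, unname(oracle["enrich"]), tolerance = 1e-14)
  expect_equal(dep, unname(oracle["deplete"]), tolerance = 1e-14)
  # category = reference -> forced full overlap, enrichment p = 1
  expect_equal(ora(ref[1:5], ref, ref, sided = "enrichment")$p_raw, 1)
  # subset precondition
  expect_error(ora(c("zz"), ref, cat2), "subset")
})

test_that("hypergeometric tail identity holds across random inputs", {
  withr::with_seed(5, {
    for (i in 1:200) {
      N <- sample(5:60, 1)
      K <- sample(1:(N - 1), 1)
      n <- sample(1:N, 1)
      k <- sample(0:min(K, n), 1)
      p_ge <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      p_le <- stats::phyper(k, K, N - K, n)
      p_eq <- stats::dhyper(k, K, N - K, n)
      expect_lt(abs(p_ge + p_le - p_eq - 1), 1e-12)
    }
  })
})

test_that("running-sum ES matches the hand-stepped example and oracle", {
  # N=3, scores (3,2,1), members at ranks 1 and 3, weight 1:
  # N_R = 4, steps 3/4, -1, 1/4 -> running 0.75, -0.25, 0
  r <- tibble::tibble(gene = c("A", "B", "C"), score = c(3, 2, 1))
  e <- gsea_es(r, c("A", "C"), weight_p = 1)
  expect_equal(e$es, 0.75, tolerance = 1e-14)
  expect_equal(e$hit_positions, c(1L, 3L))
  expect_equal(e$leading_edge, "A")
  # head-loaded category attains the maximal ES of 1 (unweighted)
  r10 <- tibble::tibble(gene = paste0("g", 1:10), score = 10:1)
  expect_equal(gsea_es(r10, paste0("g", 1:3), weight_p = 0)$es, 1)
  # reversing a symmetric-score list negates the unweighted ES
  rs <- tibble::tibble(gene = paste0("g", 1:6), score = c(3, 2, 1, -1, -2, -3))
  rev_rs <- tibble::tibble(
    gene = paste0("g", 6:1), score = c(3, 2, 1, -1, -2, -3)
  )
  cat6 <- c("g1", "g2", "g4")
  expect_equal(
    gsea_es(rev_rs, cat6, weight_p = 0)$es,
    -gsea_es(rs, cat6, weight_p = 0)$es,
    tolerance = 1e-12
  )
  # randomized agreement with the brute-force oracle, |ES| <= 1
  withr::with_seed(9, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      genes <- paste0("g", seq_len(n))
      scores <- sort(round(stats::rnorm(n), 3), decreasing = TRUE)
      ranked <- tibble::tibble(gene = genes, score = scores)
      nh <- sample(1:(n - 1), 1)
      members <- sample(genes, nh)
      for (wp in c(0, 1, 2)) {
        got <- gsea_es(ranked, members, weight_p = wp)$es
        want <- es_brute(
          ranked$score, ranked$gene %in% members, wp
        )
        expect_equal(got, want, tolerance = 1e-12)
        expect_lte(abs(got), 1 + 1e-12)
      }
    }
  })
  # category covering the whole list is undefined
  expect_error(gsea_es(r, c("A", "B", "C")), "whole")
})

test_that("permutation p-values respect the add-one bound and seed", {
  r <- tibble::tibble(gene = paste0("g", 1:30), score = 30:1)
  rec <- gsea_pvalue(r, paste0("g", 1:5), n_perm = 200, seed = 3)
  expect_gte(rec$p_raw, 1 / 201)
  expect_identical(
    rec, gsea_pvalue(r, paste0("g", 1:5), n_perm = 200, seed = 3)
  )
  expect_false(isTRUE(all.equal(
    rec$p_raw,
    gsea_pvalue(r, paste0("g", 14:18), n_perm = 200, seed = 3)$p_raw
  )))
})

test_that("random categories give roughly uniform permutation p-values", {
  withr::with_seed(21, {
    n <- 60
    ranked <- tibble::tibble(
      gene = paste0("g", 1:n),
      score = sort(stats::rnorm(n), decreasing = TRUE)
    )
    ps <- vapply(1:40, function(i) {
      gsea_pvalue(ranked, sample(ranked$gene, 8),
        n_perm = 200, seed = i, weight_p = 0
      )$p_raw
    }, numeric(1))
    # mean of Uniform(0,1) over 40 draws: SE ~ 0.0456
    expect_lt(abs(mean(ps) - 0.5), 3 * 0.0456 + 0.02)
  })
})

test_that("rank-based FCS agrees with enumeration and is antisymmetric", {
  r <- tibble::tibble(gene = paste0("g", 1:6), score = c(9, 8, 6, 4, 3, 1))
  rec <- fcs_wilcoxon(r, c("g1", "g2"))
  # exact two-sided p over all C(6,2) member placements
  combos <- utils::combn(6, 2)
  ranks <- rank(r$score)
  w_obs <- sum(ranks[1:2])
  w_null <- apply(combos, 2, function(i) sum(ranks[i]))
  mu <- mean(w_null)
  p_exact <- mean(abs(w_null - mu) >= abs(w_obs - mu))
  expect_lt(abs(rec$p_raw - p_exact), 0.08) # normal approximation at tiny N
  expect_equal(rec$direction, "enriched")
  # complement swap negates z
  z_members <- fcs_wilcoxon(r, c("g1", "g2"))$statistic
  z_complement <- fcs_wilcoxon(r, paste0("g", 3:6))$statistic
  expect_equal(z_complement, -z_members, tolerance = 1e-12)
  # members in the top half of an even list maximize |z| for that N
  z_top <- fcs_wilcoxon(r, paste0("g", 1:3))$statistic
  withr::with_seed(2, {
    for (i in 1:20) {
      z_other <- fcs_wilcoxon(r, sample(r$gene, 3))$statistic
      expect_lte(abs(z_other), abs(z_top) + 1e-12)
    }
  })
})

test_that("parametric FCS matches the Welch formula and is shift-invariant", {
  r <- tibble::tibble(gene = c("A", "B", "C", "D"), score = c(5, 4, 1, 0))
  rec <- fcs_ttest(r, c("A", "B"))
  # hand Welch: means 4.5 vs 0.5, each var 0.5 -> t = 4 / sqrt(0.5)
  expect_equal(rec$statistic, 4 / sqrt(0.5), tolerance = 1e-12)
  oracle <- stats::t.test(c(5, 4), c(1, 0))
  expect_equal(rec$p_raw, oracle$p.value, tolerance = 1e-12)
  shifted <- tibble::tibble(gene = r$gene, score = r$score + 100)
  expect_equal(
    fcs_ttest(shifted, c("A", "B"))$statistic, rec$statistic,
    tolerance = 1e-12
  )
  # balanced identical multisets give t = 0
  r0 <- tibble::tibble(gene = paste0("g", 1:4), score = c(2, 1, 2, 1))
  expect_equal(fcs_ttest(r0, c("g1", "g2"))$statistic, 0)
})

test_that("averaging FCS reports the member summary with a permutation p", {
  r <- tibble::tibble(gene = paste0("g", 1:10), score = 10:1)
  rec <- fcs_mean(r, paste0("g", 1:3), stat = "mean", n_perm = 200, seed = 1)
  expect_equal(rec$statistic, mean(10:8))
  expect_gte(rec$p_raw, 1 / 201)
  # all-equal scores -> p = 1 on the estimator grid
  re <- tibble::tibble(gene = paste0("g", 1:6), score = rep(2, 6))
  expect_equal(
    fcs_mean(re, c("g1", "g2"), n_perm = 100, seed = 1)$p_raw, 1
  )
  expect_equal(fcs_mean(re, c("g1", "g2"), n_perm = 100, seed = 1)$statistic, 2)
})

test_that("p-value adjustment follows the step-up definitions", {
  expect_equal(
    adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "benjamini_hochberg"),
    c(0.04, 0.04, 0.04, 0.04)
  )
  expect_equal(adjust_pvalues(0.2, "benjamini_hochberg"), 0.2)
  expect_equal(
    adjust_pvalues(c(0.02, 0.5), "bonferroni"), c(0.04, 1.0)
  )
  withr::with_seed(8, {
    for (i in 1:50) {
      p <- stats::runif(sample(1:40, 1))
      adj <- adjust_pvalues(p, "benjamini_hochberg")
      expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15))
      # monotone when re-sorted by raw p
      expect_true(!is.unsorted(adj[order(p)]))
    }
  })
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the enrichment driver filters, sorts, and adjusts correctly", {
  ranked <- tibble::tibble(gene = paste0("g", 1:40), score = 40:1)
  sets <- gene_sets(
    c("planted", "tiny", "huge", "mid"),
    list(
      paste0("g", 1:8),
      "g5",
      paste0("g", 1:40),
      paste0("g", 15:24)
    )
  )
  res <- run_enrichment(ranked, sets,
    method = "wilcoxon", min_size = 3, max_size = 30
  )
  expect_s3_class(res, "tk_enrichment")
  expect_equal(sort(res$category), c("mid", "planted"))
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$category, c("tiny", "huge"))
  expect_equal(res$category[1], "planted") # strongest signal first
  expect_equal(res$p_adj, adjust_pvalues(res$p_raw, "benjamini_hochberg"))
  # a single surviving category keeps p_adj = p_raw under BH
  one <- run_enrichment(ranked, sets[1, ], method = "ttest")
  expect_equal(one$p_adj, one$p_raw)
  # ORA branch: survivor count matches a direct filter
  res_ora <- run_enrichment(
    list(test = paste0("g", 1:8), reference = ranked$gene),
    sets,
    method = "ora", min_size = 3, max_size = 30
  )
  expect_equal(nrow(res_ora), 2)
  expect_error(
    run_enrichment(ranked, sets[2, ], method = "wilcoxon", min_size = 3),
    "No category"
  )
})

test_that("the planted category wins on the synthetic bulk fixture", {
  bulk <- make_bulk(42)
  scores <- score_t_test(bulk$matrix, bulk$groups)
  gs <- make_genesets(42, expr_genes(bulk$matrix), bulk$truth$de_genes)
  sel <- select_deregulated(scores, top_k = 50)
  res <- run_enrichment(
    list(test = sel, reference = scores$gene), gs$sets,
    method = "ora"
  )
  expect_equal(res$category[1], gs$truth$planted_set)
  expect_lt(res$p_adj[1], 0.05)
})
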