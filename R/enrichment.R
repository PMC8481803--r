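#' Over-representation analysis for one category
#'
#' Exact hypergeometric tail test for the overlap between a preselected gene
#' set and a biological category, relative to a reference (background) set.
#' With `N = |reference|`, `K = |category in reference|`, `n = |test set|`
#' and `k = |category in test set|`, the enrichment p-value is `P(X >= k)`
#' and the depletion p-value `P(X <= k)` for `X ~ Hypergeometric(N, K, n)`;
#' the two-sided p-value doubles the smaller tail, capped at 1. The reported
#' direction follows the sign of `k - n K / N`.
#'
#' @param test_set Character vector: the preselected (e.g. most deregulated)
#'   genes. Must be a subset of `reference_set`.
#' @param reference_set Character vector: the background universe.
#' @param category Character vector: members of the category under test
#'   (intersected with the reference before testing).
#' @param sided One of `"enrichment"`, `"depletion"`, `"two_sided"`.
#' @param name Category name recorded in the result row.
#' @return A one-row tibble with columns `category`, `category_size`,
#'   `hits`, `statistic` (the overlap `k`), `direction`, `p_raw`, `p_adj`
#'   (`NA`, filled by [run_enrichment()]), and `hit_genes` (list column).
#' @export
#' @examples
#' ora(letters[1:5], letters[1:10], letters[c(1:4, 10)])
ora <- function(test_set, reference_set, category,
                sided = c("two_sided", "enrichment", "depletion"),
                name = "category") {
  sided <- match.arg(sided)
  test_set <- unique(normalize_genes(test_set, "test set"))
  reference_set <- unique(normalize_genes(reference_set, "reference set"))
  category <- unique(normalize_genes(category, "category member"))
  if (!all(test_set %in% reference_set)) {
    stop("Test set must be a subset of the reference set (offender: ",
      setdiff(test_set, reference_set)[1], ").",
      call. = FALSE
    )
  }
  if (length(test_set) < 1) stop("Empty test set.", call. = FALSE)
  cat_ref <- intersect(category, reference_set)
  if (length(cat_ref) == 0) {
    stop("Category has no overlap with the reference set.", call. = FALSE)
  }
  N <- length(reference_set)
  K <- length(cat_ref)
  n <- length(test_set)
  hit_genes <- sort(intersect(cat_ref, test_set))
  k <- length(hit_genes)
  p_enr <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_dep <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  p <- switch(sided,
    enrichment = p_enr,
    depletion = p_dep,
    two_sided = min(1, 2 * min(p_enr, p_dep))
  )
  expected <- n * K / N
  direction <- if (k > expected) {
    "enriched"
  } else if (k < expected) {
    "depleted"
  } else {
    "none"
  }
  enrichment_record(
    category = name, category_size = K, hits = k, statistic = as.numeric(k),
    direction = direction, p_raw = p, hit_genes = hit_genes
  )
}

# Canonical one-row enrichment record.
enrichment_record <- function(category, category_size, hits, statistic,
                              direction, p_raw, hit_genes,
                              p_adj = NA_real_) {
  tibble::tibble(
    category = category,
    category_size = as.integer(category_size),
    hits = as.integer(hits),
    statistic = statistic,
    direction = direction,
    p_raw = p_raw,
    p_adj = p_adj,
    hit_genes = list(hit_genes)
  )
}

#' Running-sum (GSEA-style) enrichment score
#'
#' Walks the ranked gene list from top to bottom, incrementing the running
#' sum at category members ("hits") by `|score|^p / N_R` (with
#' `N_R = sum of |score|^p over hits`; an unweighted step `1/N_hits` is used
#' when `N_R` is zero) and decrementing at non-members by
#' `1 / (N - N_hits)`. The enrichment score ES is the running sum's maximum
#' deviation from zero, signed. `weight_p = 0` gives the classical
#' unweighted Kolmogorov-Smirnov-like statistic.
#'
#' @param ranked A data frame with columns `gene`, `score`; re-sorted
#'   descending with lexicographic tie-break.
#' @param category Character vector of category members (intersected with
#'   the list).
#' @param weight_p Non-negative score-weighting exponent (default 1).
#' @return A list with elements `es`, `leading_edge` (member genes at or
#'   before the extremum for positive ES, at or after it for negative ES),
#'   `hit_positions` (1-based ranks of members), and `running_sum`.
#' @export
gsea_es <- function(ranked, category, weight_p = 1) {
  stopifnot(weight_p >= 0)
  ranked <- as_ranked_list(ranked)
  category <- unique(normalize_genes(category, "category member"))
  n <- nrow(ranked)
  hit <- ranked$gene %in% category
  nh <- sum(hit)
  if (nh == 0) {
    stop("Category has no member in the ranked list.", call. = FALSE)
  }
  if (nh == n) {
    stop("Category covers the whole ranked list; statistic undefined.",
      call. = FALSE
    )
  }
  w <- abs(ranked$score)^weight_p
  nr <- sum(w[hit])
  steps <- numeric(n)
  if (nr > 0) {
    steps[hit] <- w[hit] / nr
  } else {
    steps[hit] <- 1 / nh
  }
  steps[!hit] <- -1 / (n - nh)
  rs <- cumsum(steps)
  i_max <- es_extremum(rs)
  es <- rs[i_max]
  hit_positions <- which(hit)
  leading <- if (es >= 0) {
    ranked$gene[hit_positions[hit_positions <= i_max]]
  } else {
    ranked$gene[hit_positions[hit_positions >= i_max]]
  }
  list(
    es = es, leading_edge = leading,
    hit_positions = hit_positions, running_sum = rs
  )
}

#' Permutation p-value for the running-sum enrichment score
#'
#' The null distribution is generated by gene-label permutation: category
#' membership is reassigned to random ranks of the same list, keeping the
#' member count fixed. The two-sided p-value uses the add-one estimator
#' `(1 + #{|ES_null| >= |ES|}) / (B + 1)`, so it is never below
#' `1 / (B + 1)`.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of membership permutations (at least 100).
#' @param seed Integer seed; identical seeds give identical output.
#' @param name Category name recorded in the result row.
#' @return A one-row enrichment record tibble (see [ora()] for columns);
#'   `statistic` is the ES and `direction` its sign.
#' @export
gsea_pvalue <- function(ranked, category, weight_p = 1, n_perm = 1000,
                        seed = 42, name = "category") {
  stopifnot(n_perm >= 100)
  ranked <- as_ranked_list(ranked)
  obs <- gsea_es(ranked, category, weight_p = weight_p)
  n <- nrow(ranked)
  nh <- length(obs$hit_positions)
  w <- abs(ranked$score)^weight_p
  miss_step <- -1 / (n - nh)
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pos <- sample.int(n, nh)
      steps <- rep(miss_step, n)
      nr <- sum(w[pos])
      steps[pos] <- if (nr > 0) w[pos] / nr else 1 / nh
      rs <- cumsum(steps)
      rs[es_extremum(rs)]
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  enrichment_record(
    category = name,
    category_size = nh,
    hits = nh,
    statistic = obs$es,
    direction = if (obs$es > 0) "enriched" else if (obs$es < 0) "depleted" else "none",
    p_raw = p,
    hit_genes = obs$leading_edge
  )
}

#' Rank-based functional class scoring (Wilcoxon)
#'
#' Compares the scores of category members against non-members with the
#' rank-sum z statistic (tie-corrected normal approximation, no continuity
#' correction); positive z means members carry higher scores.
#'
#' @inheritParams gsea_es
#' @param name Category name recorded in the result row.
#' @return A one-row enrichment record tibble; `statistic` is z and the
#'   p-value two-sided.
#' @export
fcs_wilcoxon <- function(ranked, category, name = "category") {
  ranked <- as_ranked_list(ranked)
  category <- unique(normalize_genes(category, "category member"))
  member <- ranked$gene %in% category
  nh <- sum(member)
  if (nh < 1 || nh >= nrow(ranked)) {
    stop("Category must cover between 1 and N-1 genes of the list.",
      call. = FALSE
    )
  }
  z <- rank_sum_z(ranked$score[member], ranked$score[!member])
  p <- 2 * stats::pnorm(-abs(z))
  enrichment_record(
    category = name, category_size = nh, hits = nh, statistic = z,
    direction = if (z > 0) "enriched" else if (z < 0) "depleted" else "none",
    p_raw = min(1, p),
    hit_genes = sort(ranked$gene[member])
  )
}

#' Parametric functional class scoring (Welch t)
#'
#' Welch two-sample t-test of member scores against non-member scores, with
#' a two-sided p-value from the t distribution at Welch-Satterthwaite
#' degrees of freedom.
#'
#' @inheritParams fcs_wilcoxon
#' @return A one-row enrichment record tibble, or `NULL` with a warning when
#'   the variance degenerates (category skipped).
#' @export
fcs_ttest <- function(ranked, category, name = "category") {
  ranked <- as_ranked_list(ranked)
  category <- unique(normalize_genes(category, "category member"))
  member <- ranked$gene %in% category
  nh <- sum(member)
  if (nh < 2 || nrow(ranked) - nh < 2) {
    stop("Welch FCS needs at least 2 members and 2 non-members.",
      call. = FALSE
    )
  }
  res <- welch_t_rows(
    matrix(ranked$score[member], nrow = 1),
    matrix(ranked$score[!member], nrow = 1)
  )
  if (res$degenerate[1]) {
    warning("Degenerate variance for category ", name, "; skipped.")
    return(NULL)
  }
  t <- res$t[1]
  p <- 2 * stats::pt(-abs(t), df = res$df[1])
  enrichment_record(
    category = name, category_size = nh, hits = nh, statistic = t,
    direction = if (t > 0) "enriched" else if (t < 0) "depleted" else "none",
    p_raw = min(1, p),
    hit_genes = sort(ranked$gene[member])
  )
}

#' Averaging functional class scoring
#'
#' Summarizes member scores by their mean or median and assesses the
#' summary with a membership-permutation null (add-one estimator,
#' two-sided around the corresponding summary of all scores).
#'
#' @inheritParams fcs_wilcoxon
#' @param stat `"mean"` or `"median"`.
#' @param n_perm Number of membership permutations.
#' @param seed Integer seed.
#' @return A one-row enrichment record tibble; `statistic` is the member
#'   summary.
#' @export
fcs_mean <- function(ranked, category, stat = c("mean", "median"),
                     n_perm = 1000, seed = 42, name = "category") {
  stat <- match.arg(stat)
  ranked <- as_ranked_list(ranked)
  category <- unique(normalize_genes(category, "category member"))
  member <- ranked$gene %in% category
  nh <- sum(member)
  if (nh < 1) stop("Category has no member in the list.", call. = FALSE)
  f <- if (stat == "mean") mean else stats::median
  obs <- f(ranked$score[member])
  center <- f(ranked$score)
  null_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      f(ranked$score[sample.int(nrow(ranked), nh)])
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_stats - center) >= abs(obs - center))) / (n_perm + 1)
  enrichment_record(
    category = name, category_size = nh, hits = nh, statistic = obs,
    direction = if (obs > center) {
      "enriched"
    } else if (obs < center) {
      "depleted"
    } else {
      "none"
    },
    p_raw = p,
    hit_genes = sort(ranked$gene[member])
  )
}

#' Multiple-testing adjustment
#'
#' Adjusts raw p-values, preserving input order. Benjamini-Hochberg is the
#' step-up procedure with the cumulative minimum taken from the largest
#' rank, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method One of `"benjamini_hochberg"`, `"bonferroni"`,
#'   `"benjamini_yekutieli"` (or the short aliases `"bh"`, `"by"`).
#' @return Numeric vector of adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = c(
                             "benjamini_hochberg", "bonferroni",
                             "benjamini_yekutieli", "bh", "by"
                           )) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  method <- switch(method,
    benjamini_hochberg = "BH",
    bh = "BH",
    bonferroni = "bonferroni",
    benjamini_yekutieli = "BY",
    by = "BY"
  )
  stats::p.adjust(p, method = method)
}

#' Run an enrichment analysis over a gene set collection
#'
#' The single driver behind both analysis families: over-representation
#' analysis of a preselected gene set against a reference, and
#' functional-class-scoring of a complete ranked score list. Categories are
#' intersected with the reference (ORA) or the ranked list (FCS) first;
#' those whose intersected size falls outside `[min_size, max_size]` (or
#' that do not overlap at all) are skipped with a recorded reason.
#' Adjusted p-values are computed across tested categories only.
#'
#' @param x For `method = "ora"`: a list with elements `test` and
#'   `reference` (character vectors). For FCS methods: a data frame with
#'   columns `gene` and `score`.
#' @param sets A `tk_gene_sets` collection (see [gene_sets()], [read_gmt()]).
#' @param method One of `"ora"`, `"gsea"`, `"wilcoxon"`, `"ttest"`,
#'   `"mean"`, `"median"`.
#' @param min_size,max_size Category size bounds after intersection.
#' @param adjust Adjustment method passed to [adjust_pvalues()].
#' @param sided ORA only: tail choice, see [ora()].
#' @param weight_p,n_perm,seed Passed to the permutation-based statistics.
#' @return A tibble of class `tk_enrichment`, one row per tested category,
#'   sorted by `p_raw` then category name, with attributes `method`,
#'   `adjust`, and `skipped` (a tibble of skipped categories and reasons).
#' @export
run_enrichment <- function(x, sets,
                           method = c(
                             "ora", "gsea", "wilcoxon", "ttest",
                             "mean", "median"
                           ),
                           min_size = 3, max_size = 700,
                           adjust = "benjamini_hochberg",
                           sided = "two_sided",
                           weight_p = 1, n_perm = 1000, seed = 42) {
  method <- match.arg(method)
  stopifnot(min_size >= 1, max_size >= min_size)
  if (method == "ora") {
    if (!is.list(x) || !all(c("test", "reference") %in% names(x))) {
      stop("For ORA, `x` must be list(test = ..., reference = ...).",
        call. = FALSE
      )
    }
    universe <- unique(normalize_genes(x$reference, "reference set"))
    test_set <- unique(normalize_genes(x$test, "test set"))
    if (!all(test_set %in% universe)) {
      stop("Test set must be a subset of the reference set.", call. = FALSE)
    }
  } else {
    ranked <- as_ranked_list(x)
    universe <- ranked$gene
  }

  records <- list()
  skipped <- list()
  for (i in seq_len(nrow(sets))) {
    nm <- sets$set[[i]]
    members <- intersect(sets$genes[[i]], universe)
    if (length(members) == 0) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(category = nm, reason = "no_overlap")
      next
    }
    if (length(members) < min_size || length(members) > max_size) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(category = nm, reason = "outside_size_bounds")
      next
    }
    if (method != "ora" && length(members) == length(universe)) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(category = nm, reason = "covers_whole_list")
      next
    }
    rec <- switch(method,
      ora = ora(test_set, universe, members, sided = sided, name = nm),
      gsea = gsea_pvalue(ranked, members,
        weight_p = weight_p,
        n_perm = n_perm, seed = seed, name = nm
      ),
      wilcoxon = fcs_wilcoxon(ranked, members, name = nm),
      ttest = tryCatch(fcs_ttest(ranked, members, name = nm),
        warning = function(w) NULL
      ),
      mean = fcs_mean(ranked, members,
        stat = "mean", n_perm = n_perm,
        seed = seed, name = nm
      ),
      median = fcs_mean(ranked, members,
        stat = "median", n_perm = n_perm,
        seed = seed, name = nm
      )
    )
    if (is.null(rec)) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(category = nm, reason = "degenerate_variance")
      next
    }
    records[[length(records) + 1]] <- rec
  }
  if (length(records) == 0) {
    stop("No category survived filtering; nothing to test.", call. = FALSE)
  }
  out <- dplyr::bind_rows(records)
  out$p_adj <- adjust_pvalues(out$p_raw, method = adjust)
  out <- dplyr::arrange(out, .data$p_raw, .data$category)
  attr(out, "method") <- method
  attr(out, "adjust") <- adjust
  attr(out, "skipped") <- if (length(skipped)) {
    dplyr::bind_rows(skipped)
  } else {
    tibble::tibble(category = character(), reason = character())
  }
  class(out) <- c("tk_enrichment", class(out))
  out
}
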