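# Per-gene differential scoring between two sample groups.

# Resolve a two-group assignment against the matrix columns.
# `groups` is a data frame with columns id, group; `group_a`/`group_b` pick
# and orient the two levels (defaults: sorted unique labels).
resolve_groups <- function(m, groups, group_a = NULL, group_b = NULL,
                           min_per_group = 1L) {
  stopifnot(inherits(m, "tk_expr"))
  if (!is.data.frame(groups) || !all(c("id", "group") %in% names(groups))) {
    stop("`groups` must be a data frame with columns `id` and `group`.",
      call. = FALSE
    )
  }
  ids <- colnames(m$values)
  if (!all(ids %in% groups$id)) {
    stop("Unassigned matrix column: ", setdiff(ids, groups$id)[1],
      call. = FALSE
    )
  }
  g <- groups$group[match(ids, groups$id)]
  levels <- sort(unique(g))
  group_a <- group_a %||% levels[1]
  group_b <- group_b %||% setdiff(levels, group_a)[1]
  if (is.na(group_b) || !all(c(group_a, group_b) %in% g)) {
    stop("Need two non-empty groups; got labels: ",
      paste(levels, collapse = ", "),
      call. = FALSE
    )
  }
  a <- which(g == group_a)
  b <- which(g == group_b)
  if (length(a) < min_per_group || length(b) < min_per_group) {
    stop("Each group needs at least ", min_per_group, " samples.",
      call. = FALSE
    )
  }
  list(a = a, b = b, group_a = group_a, group_b = group_b)
}

#' Log2 fold-change score
#'
#' Per gene, `log2((mean_A + pseudocount) / (mean_B + pseudocount))`.
#' Positive scores mean higher expression in group A. A pseudocount of zero
#' is only valid when no group mean is zero.
#'
#' @param m A `tk_expr` matrix (counts or non-negative normalized values).
#' @param groups Data frame with columns `id`, `group` assigning every
#'   matrix column to one of two groups.
#' @param pseudocount Non-negative stabilizer added to both group means
#'   (default 1, the convention for count data; use 0 for pre-normalized
#'   log-scale-free data with no zero means).
#' @param group_a,group_b Which label is the numerator / denominator group;
#'   default: alphabetical order.
#' @return A tibble `gene`, `score`, sorted descending by score with
#'   lexicographic tie-break.
#' @export
score_log_fold_change <- function(m, groups, pseudocount = 1,
                                  group_a = NULL, group_b = NULL) {
  stopifnot(pseudocount >= 0)
  idx <- resolve_groups(m, groups, group_a, group_b)
  x <- expr_values(m)
  if (any(x < 0)) {
    stop("Fold-change scoring requires non-negative values.", call. = FALSE)
  }
  ma <- rowMeans(x[, idx$a, drop = FALSE])
  mb <- rowMeans(x[, idx$b, drop = FALSE])
  if (pseudocount == 0 && any(ma == 0 | mb == 0)) {
    stop("Zero group mean with pseudocount 0 for gene ",
      rownames(x)[which(ma == 0 | mb == 0)[1]],
      call. = FALSE
    )
  }
  sort_scores(tibble::tibble(
    gene = rownames(x),
    score = as.numeric(log2((ma + pseudocount) / (mb + pseudocount)))
  ))
}

#' Welch t score
#'
#' Per gene, the unequal-variance two-sample t statistic (group A minus
#' group B). Genes with zero variance in both groups are assigned score 0
#' and listed in the `degenerate` attribute with a warning.
#'
#' @inheritParams score_log_fold_change
#' @return A tibble `gene`, `score` (sorted descending), with attribute
#'   `degenerate` naming zero-variance genes.
#' @export
score_t_test <- function(m, groups, group_a = NULL, group_b = NULL) {
  idx <- resolve_groups(m, groups, group_a, group_b, min_per_group = 2L)
  x <- expr_values(m)
  res <- welch_t_rows(x[, idx$a, drop = FALSE], x[, idx$b, drop = FALSE])
  if (any(res$degenerate)) {
    warning(
      sum(res$degenerate),
      " gene(s) with zero variance in both groups scored 0."
    )
  }
  out <- sort_scores(tibble::tibble(gene = rownames(x), score = as.numeric(res$t)))
  attr(out, "degenerate") <- rownames(x)[res$degenerate]
  out
}

#' Wilcoxon rank-sum z score
#'
#' Per gene, the normal-approximation z of the rank-sum statistic
#' (tie-corrected, no continuity correction); positive when group A ranks
#' higher. Genes with all values tied across both groups score 0.
#'
#' @inheritParams score_log_fold_change
#' @return A tibble `gene`, `score`, sorted descending.
#' @export
score_wilcoxon <- function(m, groups, group_a = NULL, group_b = NULL) {
  idx <- resolve_groups(m, groups, group_a, group_b)
  x <- expr_values(m)
  z <- vapply(seq_len(nrow(x)), function(i) {
    rank_sum_z(x[i, idx$a], x[i, idx$b])
  }, numeric(1))
  sort_scores(tibble::tibble(gene = rownames(x), score = z))
}

#' Absolute-value score transform
#'
#' Replaces every score by its absolute value and re-sorts descending
#' (lexicographic gene tie-break), for analyses where the direction of the
#' expression change is irrelevant. Idempotent.
#'
#' @param scores A tibble with columns `gene`, `score`.
#' @return The transformed, re-sorted score tibble.
#' @export
transform_abs <- function(scores) {
  scores <- as_ranked_list(scores, min_n = 0L)
  scores$score <- abs(scores$score)
  sort_scores(scores)
}

#' Select deregulated genes from a score list
#'
#' Exactly one filter rule must be given: `top_k` (the k highest-scoring
#' genes), `upper_lower_percent` (the top q% plus bottom q% by score, with
#' `ceiling(q/100 * n)` genes per tail), or `abs_threshold` (all genes with
#' `|score| >= t`). Ties are broken by gene token.
#'
#' @param scores A tibble with columns `gene`, `score`.
#' @param top_k Integer k, `1 <= k <= nrow(scores)`.
#' @param upper_lower_percent Percentage q in (0, 50\].
#' @param abs_threshold Threshold t >= 0.
#' @return Sorted character vector of selected gene tokens.
#' @export
select_deregulated <- function(scores, top_k = NULL,
                               upper_lower_percent = NULL,
                               abs_threshold = NULL) {
  rules <- !vapply(
    list(top_k, upper_lower_percent, abs_threshold), is.null, logical(1)
  )
  if (sum(rules) != 1) {
    stop("Give exactly one of `top_k`, `upper_lower_percent`, ",
      "`abs_threshold`.",
      call. = FALSE
    )
  }
  scores <- as_ranked_list(scores, min_n = 1L)
  n <- nrow(scores)
  if (!is.null(top_k)) {
    if (top_k < 1 || top_k > n) {
      stop("`top_k` must lie in [1, ", n, "].", call. = FALSE)
    }
    return(sort(scores$gene[seq_len(top_k)]))
  }
  if (!is.null(upper_lower_percent)) {
    q <- upper_lower_percent
    if (q <= 0 || q > 50) stop("`upper_lower_percent` in (0, 50].", call. = FALSE)
    per_tail <- ceiling(q / 100 * n)
    top <- scores$gene[seq_len(per_tail)]
    bottom_order <- order(scores$score, scores$gene)
    bottom <- scores$gene[bottom_order[seq_len(per_tail)]]
    return(sort(unique(c(top, bottom))))
  }
  if (abs_threshold < 0) stop("`abs_threshold` must be >= 0.", call. = FALSE)
  sort(scores$gene[abs(scores$score) >= abs_threshold])
}
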