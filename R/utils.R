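# Internal helpers shared across modules.

#' Normalize gene identifier tokens
#'
#' Gene identifiers are treated as opaque, case-insensitive tokens: leading
#' and trailing whitespace is stripped and the token upper-cased. Tokens must
#' be non-empty and free of tab/newline characters.
#'
#' @param x Character vector of raw gene tokens.
#' @param context String used in error messages to locate the offender.
#' @return Character vector of normalized tokens.
#' @export
normalize_genes <- function(x, context = "gene id") {
  if (!is.character(x)) {
    stop("`", context, "` must be a character vector.", call. = FALSE)
  }
  out <- toupper(trimws(x))
  bad <- !nzchar(out) | grepl("[\t\n\r]", out)
  if (any(bad)) {
    stop(
      "Invalid ", context, " at position ", which(bad)[1],
      ": empty or contains tab/newline.",
      call. = FALSE
    )
  }
  out
}

# Stable descending sort by score with lexicographic gene tie-break.
# The universal ordering convention of the package: every score list and
# ranked list is arranged this way so results are bit-reproducible.
sort_scores <- function(df) {
  stopifnot(all(c("gene", "score") %in% names(df)))
  dplyr::arrange(df, dplyr::desc(.data$score), .data$gene)
}

# Validate and canonicalize a (gene, score) tibble into a ranked list.
as_ranked_list <- function(scores, min_n = 2L) {
  if (!is.data.frame(scores) || !all(c("gene", "score") %in% names(scores))) {
    stop("A score list must be a data frame with columns `gene` and `score`.",
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(scores[c("gene", "score")])
  out$gene <- normalize_genes(out$gene)
  if (anyDuplicated(out$gene)) {
    stop("Score list contains duplicate gene: ",
      out$gene[duplicated(out$gene)][1],
      call. = FALSE
    )
  }
  if (!all(is.finite(out$score))) {
    stop("Score list contains non-finite scores.", call. = FALSE)
  }
  if (nrow(out) < min_n) {
    stop("Score list must contain at least ", min_n, " genes.", call. = FALSE)
  }
  sort_scores(out)
}

# Rank-sum z statistic with tie correction, no continuity correction.
# Positive when `x` tends to rank higher than `y`. Returns 0 when the
# variance degenerates (all values tied).
rank_sum_z <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(0)
  }
  (w - mu) / sqrt(sigma2)
}

# Vectorized Welch t over rows of two matrices (same genes, different
# sample groups). Degenerate rows (zero variance in both groups) get t = 0;
# their indices are returned so callers can warn.
welch_t_rows <- function(xa, xb) {
  na <- ncol(xa)
  nb <- ncol(xb)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  degenerate <- se2 <= 0
  t <- ifelse(degenerate, 0, (ma - mb) / sqrt(pmax(se2, .Machine$double.xmin)))
  df <- ifelse(
    degenerate, NA_real_,
    se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  )
  list(t = t, df = df, degenerate = degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Index of the running sum's extremum: the first position whose absolute
# value comes within 1e-12 of the maximum. The tolerance makes the choice
# stable when the positive and negative deviations tie in magnitude and
# floating-point accumulation order would otherwise decide the sign.
es_extremum <- function(rs) {
  which(abs(rs) >= max(abs(rs)) - 1e-12)[1]
}
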