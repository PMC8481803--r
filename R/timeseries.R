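# Time-resolved expression: change scoring, filtering, k-medoids
# clustering of time courses, per-cluster over-representation.

#' Construct a time-course set
#'
#' @param values Numeric matrix, genes x timepoints, finite, with unique
#'   gene rownames.
#' @param timepoints Strictly increasing numeric vector, one per column,
#'   at least 3.
#' @return An object of class `tk_timecourse`.
#' @export
time_course <- function(values, timepoints) {
  stopifnot(is.matrix(values))
  if (length(timepoints) != ncol(values) || length(timepoints) < 3) {
    stop("Need >= 3 timepoints matching the matrix columns.", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("Timepoints must be strictly increasing.", call. = FALSE)
  }
  if (is.null(rownames(values))) stop("Gene rownames required.", call. = FALSE)
  rownames(values) <- normalize_genes(rownames(values), "gene row")
  if (anyDuplicated(rownames(values))) {
    stop("Duplicate gene row.", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("Values must be finite.", call. = FALSE)
  colnames(values) <- as.character(timepoints)
  structure(
    list(values = values, timepoints = as.numeric(timepoints)),
    class = "tk_timecourse"
  )
}

#' @export
print.tk_timecourse <- function(x, ...) {
  cat(
    "<tk_timecourse> ", nrow(x$values), " genes x ",
    length(x$timepoints), " timepoints\n",
    sep = ""
  )
  invisible(x)
}

#' Aggregated expression change per gene
#'
#' Per gene, the sum of absolute expression differences between all
#' consecutive timepoints. Translation- and time-reversal-invariant.
#'
#' @param tc A `tk_timecourse` object.
#' @return A tibble `gene`, `score`, sorted descending.
#' @export
change_score <- function(tc) {
  stopifnot(inherits(tc, "tk_timecourse"))
  d <- abs(t(diff(t(tc$values))))
  sort_scores(tibble::tibble(
    gene = rownames(tc$values),
    score = if (ncol(tc$values) == 2) as.numeric(d) else rowSums(d)
  ))
}

#' Filter time courses to the strongest changers
#'
#' Exactly one rule: `threshold` keeps genes with change score >= the
#' value; `top_fraction` keeps the `ceiling(f * n)` genes with the highest
#' change scores (gene-token tie-break).
#'
#' @param tc A `tk_timecourse` object.
#' @param scores Optional precomputed [change_score()] tibble (recomputed
#'   when `NULL`).
#' @param threshold Non-negative change-score cutoff.
#' @param top_fraction Fraction f in (0, 1\].
#' @return The restricted `tk_timecourse`.
#' @export
filter_changing <- function(tc, scores = NULL, threshold = NULL,
                            top_fraction = NULL) {
  stopifnot(inherits(tc, "tk_timecourse"))
  if (is.null(threshold) == is.null(top_fraction)) {
    stop("Give exactly one of `threshold`, `top_fraction`.", call. = FALSE)
  }
  scores <- scores %||% change_score(tc)
  scores <- sort_scores(tibble::as_tibble(scores))
  keep <- if (!is.null(threshold)) {
    if (threshold < 0) stop("`threshold` must be >= 0.", call. = FALSE)
    scores$gene[scores$score >= threshold]
  } else {
    if (top_fraction <= 0 || top_fraction > 1) {
      stop("`top_fraction` must lie in (0, 1].", call. = FALSE)
    }
    scores$gene[seq_len(ceiling(top_fraction * nrow(scores)))]
  }
  if (length(keep) == 0) stop("No gene passes the filter.", call. = FALSE)
  keep <- intersect(rownames(tc$values), keep)
  time_course(tc$values[keep, , drop = FALSE], tc$timepoints)
}

# z-normalize rows; constant rows become all-zero (flagged by caller).
z_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  out <- (x - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Cluster expression time courses (k-medoids)
#'
#' Partitions the filtered genes into `k` clusters by seeded k-medoids:
#' medoids initialized as k distinct random genes, then alternating
#' nearest-medoid assignment and within-cluster medoid update (ties broken
#' by gene token) until assignments stabilize or 100 iterations. The
#' objective (sum of distances to the assigned medoid) is non-increasing
#' across iterations and is reported. Distances: `euclidean_z` z-normalizes
#' each course first; `one_minus_pearson` uses `1 - r`. Constant courses
#' have undefined Pearson distance; they are assigned by a zero-distance
#' convention and flagged.
#'
#' @param tc A `tk_timecourse` (already filtered).
#' @param k Number of clusters, `2 <= k <=` number of genes.
#' @param distance `"euclidean_z"` or `"one_minus_pearson"`.
#' @param seed Integer seed for the medoid initialization.
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `tk_clusters`: list with `assignment`
#'   (tibble `gene`, `cluster`), `centroids` (k x timepoints matrix of
#'   member means), `medoids` (gene tokens), `objective`, `iterations`,
#'   `flagged` (constant-course genes), `timepoints`.
#' @export
cluster_timecourses <- function(tc, k,
                                distance = c(
                                  "euclidean_z", "one_minus_pearson"
                                ),
                                seed = 42, max_iter = 100) {
  distance <- match.arg(distance)
  stopifnot(inherits(tc, "tk_timecourse"))
  x <- tc$values
  n <- nrow(x)
  if (k < 2 || k > n) stop("`k` must lie in [2, #genes].", call. = FALSE)
  genes <- rownames(x)
  const <- apply(x, 1, stats::sd) == 0
  if (distance == "euclidean_z") {
    z <- z_rows(x)
    d <- as.matrix(stats::dist(z))
  } else {
    r <- suppressWarnings(stats::cor(t(x)))
    d <- 1 - r
    d[!is.finite(d)] <- 0 # zero-distance convention for constant courses
    diag(d) <- 0
  }
  res <- withr::with_seed(seed, {
    medoids <- sort(sample.int(n, k))
    assign_prev <- rep(0L, n)
    objective <- Inf
    iter <- 0L
    repeat {
      iter <- iter + 1L
      dm <- d[, medoids, drop = FALSE]
      assign <- max.col(-dm, ties.method = "first")
      # every medoid owns itself even under distance ties
      assign[medoids] <- seq_len(k)
      for (c_i in seq_len(k)) {
        members <- which(assign == c_i)
        within <- d[members, members, drop = FALSE]
        costs <- rowSums(within)
        best <- members[order(costs, genes[members])][1]
        medoids[c_i] <- best
      }
      obj <- sum(d[cbind(seq_len(n), medoids[assign])])
      if (obj > objective + 1e-12) {
        stop("Internal error: k-medoids objective increased.", call. = FALSE)
      }
      objective <- obj
      if (identical(assign, assign_prev) || iter >= max_iter) break
      assign_prev <- assign
    }
    list(assign = assign, medoids = medoids, objective = objective,
      iterations = iter)
  })
  centroids <- t(vapply(seq_len(k), function(c_i) {
    colMeans(x[res$assign == c_i, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(centroids) <- paste0("cluster_", seq_len(k))
  structure(
    list(
      assignment = tibble::tibble(gene = genes, cluster = res$assign),
      centroids = centroids,
      medoids = genes[res$medoids],
      objective = res$objective,
      iterations = res$iterations,
      flagged = genes[const & distance == "one_minus_pearson"],
      timepoints = tc$timepoints
    ),
    class = "tk_clusters"
  )
}

#' @export
print.tk_clusters <- function(x, ...) {
  cat(
    "<tk_clusters> ", nrow(x$assignment), " genes in ",
    nrow(x$centroids), " clusters; objective ",
    format(x$objective, digits = 6), " after ", x$iterations,
    " iteration(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Per-cluster over-representation analysis
#'
#' Runs an ORA ([run_enrichment()]) of each cluster's member genes against
#' the reference universe, adjusting p-values within each cluster.
#'
#' @param clusters A `tk_clusters` object.
#' @param sets A `tk_gene_sets` collection.
#' @param reference Character vector covering all clustered genes.
#' @param min_size,max_size,adjust Passed to [run_enrichment()].
#' @param sided ORA tail (default `"two_sided"`).
#' @return A tibble: cluster column plus the enrichment record columns,
#'   `p_adj` computed within cluster.
#' @export
cluster_ora <- function(clusters, sets, reference, min_size = 1,
                        max_size = 700, adjust = "benjamini_hochberg",
                        sided = "two_sided") {
  stopifnot(inherits(clusters, "tk_clusters"))
  reference <- unique(normalize_genes(reference, "reference gene"))
  if (!all(clusters$assignment$gene %in% reference)) {
    stop("Reference must cover all clustered genes.", call. = FALSE)
  }
  ids <- sort(unique(clusters$assignment$cluster))
  purrr::map_dfr(ids, function(c_i) {
    members <- clusters$assignment$gene[clusters$assignment$cluster == c_i]
    rec <- run_enrichment(
      list(test = members, reference = reference), sets,
      method = "ora", min_size = min_size, max_size = max_size,
      adjust = adjust, sided = sided
    )
    dplyr::bind_cols(tibble::tibble(cluster = c_i), tibble::as_tibble(rec))
  })
}
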