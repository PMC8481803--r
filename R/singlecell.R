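# Per-cell enrichment workflow: QC, normalization, top-N selection,
# per-cell over-representation, group activity testing, pseudo-bulk.

#' Quality-control filter for single-cell counts
#'
#' Keeps cells whose detected-gene count (genes with count > 0) lies in
#' `[min_genes, max_genes]` and whose total counts do not exceed
#' `max_total`. Genes detected in no remaining cell are dropped. Removal
#' counts per criterion are recorded in the `qc_log` attribute.
#'
#' @param m A `tk_expr` matrix in counts mode.
#' @param min_genes,max_genes Detected-gene bounds (defaults 200 and 6000).
#' @param max_total Maximum total counts per cell (default `Inf`).
#' @return The filtered `tk_expr` counts matrix.
#' @export
qc_filter <- function(m, min_genes = 200, max_genes = 6000,
                      max_total = Inf) {
  stopifnot(inherits(m, "tk_expr"))
  if (m$mode != "counts") stop("QC filtering requires counts.", call. = FALSE)
  x <- expr_values(m)
  detected <- colSums(x > 0)
  total <- colSums(x)
  low <- detected < min_genes
  high <- detected > max_genes
  over <- total > max_total
  keep <- !(low | high | over)
  if (!any(keep)) stop("No cell survives QC.", call. = FALSE)
  x2 <- x[, keep, drop = FALSE]
  gene_keep <- rowSums(x2 > 0) > 0
  out <- expr_mat(
    x2[gene_keep, , drop = FALSE],
    col_data = m$col_data[keep, ],
    mode = "counts"
  )
  attr(out, "qc_log") <- tibble::tibble(
    criterion = c("too_few_genes", "too_many_genes", "total_counts",
      "undetected_genes_dropped"),
    removed = c(sum(low), sum(high & !low), sum(over & !low & !high),
      sum(!gene_keep))
  )
  out
}

#' Normalize single-cell counts
#'
#' Scales each cell to `scale_factor` total counts (counts-per-10k by
#' default) and applies `log(1 + x)`. Every cell must have positive total
#' counts (run [qc_filter()] first).
#'
#' @param m A `tk_expr` counts matrix.
#' @param scale_factor Per-cell target total before the log (default 1e4;
#'   use 1e6 for CPM).
#' @return A `tk_expr` matrix in normalized mode.
#' @export
normalize_cells <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "tk_expr"))
  if (m$mode != "counts") stop("Normalization expects counts.", call. = FALSE)
  x <- expr_values(m)
  tot <- colSums(x)
  if (any(tot == 0)) {
    stop("Zero-total cell: ", colnames(x)[which(tot == 0)[1]],
      " (remove by QC first).",
      call. = FALSE
    )
  }
  norm <- log1p(sweep(x, 2, tot / scale_factor, "/"))
  expr_mat(norm, col_data = m$col_data, mode = "normalized")
}

#' Top expressed genes per cell
#'
#' For each cell, selects the `n` detected genes with the highest
#' normalized expression; boundary ties are broken lexicographically by
#' gene token. Cells with fewer than `n` detected genes use all their
#' detected genes and are flagged.
#'
#' @param m A `tk_expr` matrix (normalized; zero means undetected).
#' @param n Number of genes per cell (default 500).
#' @return A tibble with columns `cell`, `genes` (list column),
#'   `n_detected`, `truncated` (TRUE when fewer than `n` genes were
#'   available).
#' @export
top_n_genes <- function(m, n = 500) {
  stopifnot(inherits(m, "tk_expr"), n >= 1)
  x <- expr_values(m)
  genes <- rownames(x)
  res <- purrr::map(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    det <- which(v > 0)
    ord <- det[order(-v[det], genes[det])]
    take <- utils::head(ord, n)
    list(
      genes = genes[take],
      n_detected = length(det),
      truncated = length(det) < n
    )
  })
  tibble::tibble(
    cell = colnames(x),
    genes = purrr::map(res, "genes"),
    n_detected = purrr::map_int(res, "n_detected"),
    truncated = purrr::map_lgl(res, "truncated")
  )
}

#' Per-cell over-representation activity
#'
#' Runs an enrichment-sided hypergeometric test of each cell's top-N gene
#' set against every surviving category, with the full filtered gene
#' universe as reference. The activity score is `-log10` of the raw
#' per-cell p-value. The category filter (`[min_size, max_size]` by
#' members in the reference) is identical for every cell.
#'
#' @param top Output of [top_n_genes()].
#' @param sets A `tk_gene_sets` collection.
#' @param reference Character vector: all genes of the filtered matrix.
#' @param min_size,max_size Category size bounds after intersection with
#'   the reference.
#' @param cell_data Optional tibble of cell metadata (`id` column matching
#'   `top$cell`) carried into the result for group testing.
#' @return An object of class `tk_cell_activity`: list with `activity`
#'   (cells x categories matrix of `-log10 p`), `p` (raw p matrix),
#'   `cell_data`, and `skipped` (categories excluded, with reasons).
#' @export
per_cell_ora <- function(top, sets, reference, min_size = 3, max_size = 700,
                         cell_data = NULL) {
  reference <- unique(normalize_genes(reference, "reference gene"))
  n_ref <- length(reference)
  kept <- list()
  skipped <- list()
  for (i in seq_len(nrow(sets))) {
    members <- intersect(sets$genes[[i]], reference)
    if (length(members) == 0) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(category = sets$set[[i]], reason = "no_overlap")
    } else if (length(members) < min_size || length(members) > max_size) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(category = sets$set[[i]], reason = "outside_size_bounds")
    } else {
      kept[[sets$set[[i]]]] <- members
    }
  }
  if (length(kept) == 0) {
    stop("No category survives the size filter.", call. = FALSE)
  }
  # membership indicator (genes x categories) for vectorized overlap counts
  memb <- vapply(kept, function(g) reference %in% g, logical(n_ref))
  topmat <- vapply(
    top$genes, function(g) reference %in% g, logical(n_ref)
  )
  k <- crossprod(memb, topmat) # categories x cells overlap counts
  K <- colSums(memb)
  n_test <- colSums(topmat)
  p <- matrix(NA_real_, nrow = ncol(topmat), ncol = length(kept),
    dimnames = list(top$cell, names(kept))
  )
  for (ci in seq_along(kept)) {
    p[, ci] <- stats::phyper(
      k[ci, ] - 1, K[ci], n_ref - K[ci], n_test,
      lower.tail = FALSE
    )
  }
  if (is.null(cell_data)) {
    cell_data <- tibble::tibble(id = top$cell)
  } else {
    cell_data <- tibble::as_tibble(cell_data)
    stopifnot("id" %in% names(cell_data))
    cell_data <- cell_data[match(top$cell, cell_data$id), ]
  }
  structure(
    list(
      activity = -log10(p),
      p = p,
      cell_data = cell_data,
      skipped = if (length(skipped)) {
        dplyr::bind_rows(skipped)
      } else {
        tibble::tibble(category = character(), reason = character())
      }
    ),
    class = "tk_cell_activity"
  )
}

#' @export
print.tk_cell_activity <- function(x, ...) {
  cat(
    "<tk_cell_activity> ", nrow(x$activity), " cells x ",
    ncol(x$activity), " categories\n",
    sep = ""
  )
  invisible(x)
}

#' Test category activity differences between cell groups
#'
#' For every category and group, compares the group's per-cell activity
#' scores against all other cells with the rank-sum z statistic
#' (one-vs-rest, two-sided p). Direction is `more_active` when the group's
#' activities rank higher. P-values are adjusted across all
#' (category, group) pairs. Groups with fewer than 3 cells are excluded
#' with a warning.
#'
#' @param a A `tk_cell_activity` object.
#' @param group_key Name of the grouping column in `a$cell_data`.
#' @param adjust Adjustment method for [adjust_pvalues()].
#' @return A tibble with columns `category`, `group`, `direction`,
#'   `statistic`, `p_raw`, `p_adj`, sorted by `p_raw`.
#' @export
group_activity_test <- function(a, group_key = "group",
                                adjust = "benjamini_hochberg") {
  stopifnot(inherits(a, "tk_cell_activity"))
  if (!group_key %in% names(a$cell_data)) {
    stop("Missing grouping column: ", group_key, call. = FALSE)
  }
  g <- as.character(a$cell_data[[group_key]])
  if (anyNA(g)) stop("Every cell needs a group label.", call. = FALSE)
  counts <- table(g)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    warning("Excluding group(s) with < 3 cells: ",
      paste(small, collapse = ", "))
  }
  groups <- setdiff(sort(names(counts)), small)
  if (length(groups) < 2) {
    stop("Need at least 2 groups with >= 3 cells.", call. = FALSE)
  }
  act <- a$activity
  rows <- purrr::map(colnames(act), function(cat_name) {
    purrr::map(groups, function(grp) {
      in_grp <- g == grp
      z <- rank_sum_z(act[in_grp, cat_name], act[!in_grp, cat_name])
      tibble::tibble(
        category = cat_name,
        group = grp,
        direction = if (z >= 0) "more_active" else "less_active",
        statistic = z,
        p_raw = min(1, 2 * stats::pnorm(-abs(z)))
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out$p_adj <- adjust_pvalues(out$p_raw, method = adjust)
  dplyr::arrange(out, .data$p_raw, .data$category, .data$group)
}

#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums counts gene-wise over the cells of each sample, producing a
#' bulk-like counts matrix with one column per sample. Total counts are
#' conserved exactly.
#'
#' @param m A `tk_expr` counts matrix.
#' @param sample_key Name of the sample column in the cell metadata.
#' @return A `tk_expr` counts matrix, columns = samples.
#' @export
pseudo_bulk <- function(m, sample_key = "sample") {
  stopifnot(inherits(m, "tk_expr"))
  if (m$mode != "counts") stop("Pseudo-bulk expects counts.", call. = FALSE)
  if (!sample_key %in% names(m$col_data)) {
    stop("Missing sample column: ", sample_key, call. = FALSE)
  }
  labels <- as.character(m$col_data[[sample_key]])
  if (anyNA(labels)) {
    stop("Unlabeled cell: ", m$col_data$id[which(is.na(labels))[1]],
      call. = FALSE
    )
  }
  x <- expr_values(m)
  samples <- sort(unique(labels))
  agg <- vapply(samples, function(s) {
    rowSums(x[, labels == s, drop = FALSE])
  }, numeric(nrow(x)))
  colnames(agg) <- samples
  expr_mat(agg, mode = "counts")
}
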