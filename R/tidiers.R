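# broom-style tidiers for the fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname tk_tidiers
#' @param x A trailkit result object.
#' @param ... Ignored.
tidy.tk_enrichment <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$hit_genes <- NULL
  out
}

#' Tidiers for trailkit result objects
#'
#' `tidy()` returns the per-item results as a plain tibble; `glance()`
#' returns a one-row summary.
#'
#' @name tk_tidiers
#' @param x A trailkit result object.
#' @param alpha Significance cutoff used by the `n_significant` summary
#'   column.
#' @param ... Ignored.
NULL

#' @export
#' @rdname tk_tidiers
glance.tk_enrichment <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    method = attr(x, "method") %||% NA_character_,
    adjust = attr(x, "adjust") %||% NA_character_,
    n_tested = nrow(x),
    n_skipped = nrow(attr(x, "skipped") %||% tibble::tibble()),
    n_significant = sum(x$p_adj <= alpha, na.rm = TRUE)
  )
}

#' @export
#' @rdname tk_tidiers
tidy.tk_regulators <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
#' @rdname tk_tidiers
glance.tk_regulators <- function(x, alpha = 0.05, ...) {
  sig <- x[x$p_adj <= alpha, ]
  tibble::tibble(
    n_tested = nrow(x),
    n_excluded = nrow(attr(x, "excluded") %||% tibble::tibble()),
    n_significant = nrow(sig),
    n_activators = sum(sig$role == "activator"),
    n_repressors = sum(sig$role == "repressor")
  )
}

#' @export
#' @rdname tk_tidiers
tidy.tk_clusters <- function(x, ...) {
  x$assignment
}

#' @export
#' @rdname tk_tidiers
glance.tk_clusters <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$centroids),
    n_genes = nrow(x$assignment),
    objective = x$objective,
    iterations = x$iterations,
    n_flagged = length(x$flagged)
  )
}

#' @export
#' @rdname tk_tidiers
tidy.tk_cell_activity <- function(x, ...) {
  out <- tibble::as_tibble(x$activity, rownames = "cell")
  tidyr::pivot_longer(out, -"cell",
    names_to = "category", values_to = "activity"
  )
}

#' @export
#' @rdname tk_tidiers
glance.tk_cell_activity <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$activity),
    n_categories = ncol(x$activity),
    n_skipped = nrow(x$skipped)
  )
}

#' @export
#' @rdname tk_tidiers
tidy.tk_paths <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$nodes <- NULL
  out
}

#' @export
#' @rdname tk_tidiers
glance.tk_paths <- function(x, ...) {
  tibble::tibble(
    n_lengths = nrow(x),
    best_score = max(x$score),
    pruned_nodes = attr(x, "pruned_nodes") %||% 0L,
    n_omitted = nrow(attr(x, "omitted") %||% tibble::tibble())
  )
}
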