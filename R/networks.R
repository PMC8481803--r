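#' Construct a directed gene network
#'
#' The network is an edge tibble with columns `from` and `to` holding
#' case-normalized gene tokens. Self-loops are dropped (and counted in the
#' `self_loops_dropped` attribute) and duplicate edges collapsed.
#'
#' @param from,to Character vectors of equal length: edge endpoints.
#' @return A tibble of class `tk_network` with attributes
#'   `self_loops_dropped` and `duplicates_dropped`.
#' @export
gene_network <- function(from, to) {
  stopifnot(length(from) == length(to))
  edges <- tibble::tibble(
    from = normalize_genes(from, "edge source"),
    to = normalize_genes(to, "edge target")
  )
  loops <- edges$from == edges$to
  edges <- edges[!loops, ]
  dup <- duplicated(edges)
  edges <- edges[!dup, ]
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  attr(edges, "self_loops_dropped") <- sum(loops)
  attr(edges, "duplicates_dropped") <- sum(dup)
  class(edges) <- c("tk_network", class(edges))
  edges
}

#' Read a directed edge list
#'
#' Supports two dialects: `tsv2col` (lines of `source<TAB>target`) and `sif`
#' (lines of `source<TAB>relation<TAB>target`; the relation is ignored).
#' Deduplication and self-loop removal follow [gene_network()].
#'
#' @param path Path to the edge file.
#' @param dialect `"tsv2col"` or `"sif"`.
#' @return A `tk_network` edge tibble.
#' @export
read_edge_list <- function(path, dialect = c("tsv2col", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("Edge file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(gene_network(character(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (dialect == "tsv2col") 2L else 3L
  arity <- lengths(fields)
  if (any(arity != want)) {
    stop("Malformed edge line ", which(arity != want)[1], ": expected ",
      want, " tab-separated fields.",
      call. = FALSE
    )
  }
  src <- vapply(fields, `[[`, character(1), 1)
  dst <- vapply(fields, `[[`, character(1), want)
  gene_network(src, dst)
}

#' Write a directed edge list as two-column TSV
#'
#' @param net A `tk_network` edge tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_lines(paste(net$from, net$to, sep = "\t"), path)
  invisible(path)
}

# All node ids appearing in an edge tibble.
network_nodes <- function(net) sort(unique(c(net$from, net$to)))
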