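#' Construct a gene set collection
#'
#' A gene set collection is a tibble with one row per biological category and
#' columns `set` (unique name), `description`, and `genes` (a list column of
#' unique, case-normalized member tokens). This is the container consumed by
#' every enrichment function in the package.
#'
#' @param set Character vector of set names (unique, non-empty).
#' @param genes List of character vectors, one per set.
#' @param description Character vector of free-text descriptions (recycled
#'   empty string by default).
#' @return A tibble of class `tk_gene_sets`.
#' @export
#' @examples
#' gene_sets(c("s1", "s2"), list(c("a", "b"), c("b", "c")))
gene_sets <- function(set, genes, description = "") {
  if (length(set) == 0) {
    out <- tibble::tibble(
      set = character(), description = character(), genes = list()
    )
    class(out) <- c("tk_gene_sets", class(out))
    return(out)
  }
  stopifnot(is.character(set), is.list(genes), length(set) == length(genes))
  if (any(!nzchar(set))) stop("Gene set names must be non-empty.", call. = FALSE)
  if (anyDuplicated(set)) {
    stop("Duplicate gene set name: ", set[duplicated(set)][1], call. = FALSE)
  }
  genes <- purrr::imap(genes, function(g, i) {
    g <- unique(normalize_genes(g, context = paste0("member of set ", set[[i]])))
    if (length(g) == 0) {
      stop("Gene set ", set[[i]], " has no members.", call. = FALSE)
    }
    g
  })
  out <- tibble::tibble(
    set = set,
    description = rep_len(as.character(description), length(set)),
    genes = genes
  )
  class(out) <- c("tk_gene_sets", class(out))
  out
}

#' Read a GMT gene set file
#'
#' Parses the standard tab-separated GMT dialect: one set per line with at
#' least three fields (name, description, then one or more member genes).
#' Member tokens are case-normalized and duplicates within a line collapsed;
#' the description is preserved verbatim.
#'
#' @param path Path to a GMT file.
#' @return A `tk_gene_sets` tibble (see [gene_sets()]).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(gene_sets(character(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  arity <- lengths(fields)
  if (any(arity < 3)) {
    stop("Malformed GMT line ", which(arity < 3)[1],
      ": fewer than 3 tab-separated fields.",
      call. = FALSE
    )
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("Duplicate gene set name in GMT: ", nm[duplicated(nm)][1],
      call. = FALSE
    )
  }
  gene_sets(
    set = nm,
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write a gene set collection to GMT
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, p))` reproduces `x`
#' field-for-field.
#'
#' @param sets A `tk_gene_sets` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    sets[c("set", "description", "genes")],
    function(set, description, genes) {
      paste(c(set, description, genes), collapse = "\t")
    }
  )
  readr::write_lines(lines, path)
  invisible(path)
}
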