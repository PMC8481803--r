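#' Write enrichment records to TSV
#'
#' Writes the fixed eight-column record layout (`category`,
#' `category_size`, `hits`, `statistic`, `direction`, `p_raw`, `p_adj`,
#' `hit_genes` comma-joined), preceded by a `#`-comment line recording the
#' adjustment method shared by all records. Numeric fields survive a
#' write/read round trip to full double precision.
#'
#' @param records A `tk_enrichment` tibble (or any tibble with the record
#'   columns).
#' @param path Output path.
#' @param adjust Adjustment method recorded in the header comment; defaults
#'   to the records' own `adjust` attribute.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(records, path, adjust = NULL) {
  adjust <- adjust %||% attr(records, "adjust") %||% "benjamini_hochberg"
  cols <- c(
    "category", "category_size", "hits", "statistic", "direction",
    "p_raw", "p_adj"
  )
  df <- tibble::as_tibble(as.data.frame(records)[, c(cols, "hit_genes")])
  df$hit_genes <- vapply(
    df$hit_genes, function(g) paste(g, collapse = ","), character(1)
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# adjust=", adjust), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    num <- function(x) {
      vapply(x, function(v) format(v, digits = 17, scientific = FALSE),
        character(1)
      )
    }
    body <- paste(
      df$category, df$category_size, df$hits, num(df$statistic),
      df$direction, num(df$p_raw),
      ifelse(is.na(df$p_adj), "NA", num(df$p_adj)),
      df$hit_genes,
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}

#' Read enrichment records written by [write_enrichment_tsv()]
#'
#' @param path Path to the TSV file.
#' @return A `tk_enrichment` tibble with an `adjust` attribute recovered
#'   from the header comment.
#' @export
read_enrichment_tsv <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  adjust <- NA_character_
  if (length(lines) && startsWith(lines[1], "# adjust=")) {
    adjust <- sub("^# adjust=", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) == 0) stop("Missing header row.", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad)) {
    stop("Malformed enrichment row at data line ", bad[1], ".", call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  if (length(body) == 0) {
    out <- enrichment_record(
      character(), integer(), integer(), numeric(), character(),
      numeric(), list()
    )[0, ]
  } else {
    out <- tibble::tibble(
      category = col(1),
      category_size = as.integer(col(2)),
      hits = as.integer(col(3)),
      statistic = as.numeric(col(4)),
      direction = col(5),
      p_raw = as.numeric(col(6)),
      p_adj = suppressWarnings(as.numeric(col(7))),
      hit_genes = lapply(
        strsplit(col(8), ",", fixed = TRUE),
        function(g) g[nzchar(g)]
      )
    )
  }
  attr(out, "adjust") <- adjust
  class(out) <- c("tk_enrichment", class(out))
  out
}
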