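#' Read a two-column gene score TSV
#'
#' Accepts `gene<TAB>score` lines, with or without a `gene score` header
#' row. Returns the list sorted descending with lexicographic tie-break.
#'
#' @param path Path to the score file.
#' @return A tibble `gene`, `score`.
#' @export
read_scores_tsv <- function(path) {
  if (!file.exists(path)) stop("Score file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad)) {
    stop("Malformed score line ", bad[1], ": expected 2 fields.",
      call. = FALSE
    )
  }
  if (length(fields) &&
    is.na(suppressWarnings(as.numeric(fields[[1]][2])))) {
    fields <- fields[-1] # header row
  }
  if (length(fields) == 0) stop("Empty score file.", call. = FALSE)
  score <- suppressWarnings(
    as.numeric(vapply(fields, `[[`, character(1), 2))
  )
  if (anyNA(score)) {
    stop("Non-numeric score at line ", which(is.na(score))[1], ".",
      call. = FALSE
    )
  }
  sort_scores(tibble::tibble(
    gene = normalize_genes(vapply(fields, `[[`, character(1), 1)),
    score = score
  ))
}

#' Write a gene score list as two-column TSV
#'
#' @param scores A tibble `gene`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  scores <- sort_scores(tibble::as_tibble(scores))
  readr::write_lines(
    c(
      "gene\tscore",
      paste(scores$gene,
        vapply(scores$score, function(v) {
          format(v, digits = 17, scientific = FALSE)
        }, character(1)),
        sep = "\t"
      )
    ),
    path
  )
  invisible(path)
}
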