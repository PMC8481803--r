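#' Construct an expression matrix container
#'
#' Holds a genes-by-columns matrix of finite values together with a
#' column-metadata tibble. Columns are samples for bulk data and cells for
#' single-cell data. In `counts` mode values must be non-negative.
#'
#' @param values Numeric matrix (base or `Matrix` sparse) with unique
#'   rownames (genes) and unique colnames (sample/cell ids).
#' @param col_data Optional tibble of column metadata; must contain an `id`
#'   column matching the matrix colnames. Extra columns (e.g. `group`,
#'   `sample`, `time`, `cluster`, embedding coordinates) are carried along.
#' @param mode Either `"counts"` or `"normalized"`.
#' @return An object of class `tk_expr`.
#' @export
expr_mat <- function(values, col_data = NULL, mode = c("normalized", "counts")) {
  mode <- match.arg(mode)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("Expression matrix needs rownames (genes) and colnames (ids).",
      call. = FALSE
    )
  }
  rownames(values) <- normalize_genes(rownames(values), context = "gene row")
  if (anyDuplicated(rownames(values))) {
    stop("Duplicate gene row: ",
      rownames(values)[duplicated(rownames(values))][1],
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(values))) {
    stop("Duplicate column id: ",
      colnames(values)[duplicated(colnames(values))][1],
      call. = FALSE
    )
  }
  dense_check <- if (methods::is(values, "Matrix")) values@x else values
  if (length(dense_check) && any(!is.finite(dense_check))) {
    stop("Expression values must be finite.", call. = FALSE)
  }
  if (mode == "counts" && length(dense_check) && any(dense_check < 0)) {
    stop("Counts mode forbids negative values.", call. = FALSE)
  }
  if (is.null(col_data)) {
    col_data <- tibble::tibble(id = colnames(values))
  } else {
    col_data <- tibble::as_tibble(col_data)
    if (!"id" %in% names(col_data)) {
      stop("`col_data` must contain an `id` column.", call. = FALSE)
    }
    if (!setequal(col_data$id, colnames(values)) ||
      anyDuplicated(col_data$id)) {
      stop("`col_data$id` must match matrix colnames one-to-one.",
        call. = FALSE
      )
    }
    col_data <- col_data[match(colnames(values), col_data$id), ]
  }
  structure(
    list(values = values, col_data = col_data, mode = mode),
    class = "tk_expr"
  )
}

#' @export
print.tk_expr <- function(x, ...) {
  cat(
    "<tk_expr> ", nrow(x$values), " genes x ", ncol(x$values), " columns (",
    x$mode, ")\n",
    sep = ""
  )
  cat("col_data columns:", paste(names(x$col_data), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname expr_mat
#' @param x A `tk_expr` object.
#' @export
expr_values <- function(x) {
  stopifnot(inherits(x, "tk_expr"))
  as.matrix(x$values)
}

#' @rdname expr_mat
#' @export
expr_col_data <- function(x) {
  stopifnot(inherits(x, "tk_expr"))
  x$col_data
}

#' @rdname expr_mat
#' @export
expr_genes <- function(x) rownames(x$values)

#' Read a dense expression matrix from TSV
#'
#' Expects a header row of column ids, a first column of gene ids, and a
#' numeric body. Duplicate genes or column ids and non-numeric cells are
#' rejected with a located error.
#'
#' @param path Path to the TSV file.
#' @param mode `"counts"` or `"normalized"` (see [expr_mat()]).
#' @param col_data Optional metadata tibble passed through to [expr_mat()].
#' @return A `tk_expr` object.
#' @export
read_expression_tsv <- function(path, mode = c("normalized", "counts"),
                                col_data = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    stop("Expression file not found: ", path, call. = FALSE)
  }
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t",
    fixed = TRUE
  )[[1]]
  if (anyDuplicated(header[-1])) {
    stop("Duplicate column id in header: ",
      header[-1][duplicated(header[-1])][1],
      call. = FALSE
    )
  }
  tab <- utils::read.delim(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  if (ncol(tab) < 2) {
    stop("Expression TSV needs a gene column plus at least one sample.",
      call. = FALSE
    )
  }
  genes <- tab[[1]]
  body <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(
      "Non-numeric expression value at data row ", bad[["row"]],
      ", column '", colnames(body)[bad[["col"]]], "'.",
      call. = FALSE
    )
  }
  rownames(num) <- genes
  colnames(num) <- colnames(body)
  expr_mat(num, col_data = col_data, mode = mode)
}

#' Write an expression matrix to TSV
#'
#' @param x A `tk_expr` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  m <- expr_values(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sparse single-cell counts matrix (Matrix Market)
#'
#' Reads the MTX + row index + column index triplet commonly used for
#' single-cell counts. Gene and cell index files are one id per line
#' (a first tab-separated field is used if lines carry more).
#'
#' @param mtx_path Matrix Market file (genes x cells).
#' @param genes_path One gene id per line, in matrix row order.
#' @param cells_path One cell barcode per line, in matrix column order.
#' @param col_data Optional cell metadata tibble with an `id` column.
#' @return A `tk_expr` object in counts mode (kept sparse internally).
#' @export
read_expression_mtx <- function(mtx_path, genes_path, cells_path,
                                col_data = NULL) {
  for (p in c(mtx_path, genes_path, cells_path)) {
    if (!file.exists(p)) stop("File not found: ", p, call. = FALSE)
  }
  m <- Matrix::readMM(mtx_path)
  first_field <- function(path) {
    vapply(
      strsplit(readr::read_lines(path), "\t", fixed = TRUE),
      `[[`, character(1), 1
    )
  }
  genes <- first_field(genes_path)
  cells <- first_field(cells_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("MTX dimensions do not match gene/cell index files.", call. = FALSE)
  }
  rownames(m) <- genes
  colnames(m) <- cells
  expr_mat(m, col_data = col_data, mode = "counts")
}

#' Write a counts matrix as Matrix Market plus index files
#'
#' @param x A `tk_expr` object in counts mode.
#' @param mtx_path,genes_path,cells_path Output paths for the triplet.
#' @return `mtx_path`, invisibly.
#' @export
write_expression_mtx <- function(x, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(x, "tk_expr"))
  m <- methods::as(methods::as(Matrix::Matrix(expr_values(x), sparse = TRUE),
    "generalMatrix"
  ), "CsparseMatrix")
  Matrix::writeMM(m, mtx_path)
  readr::write_lines(rownames(x$values), genes_path)
  readr::write_lines(colnames(x$values), cells_path)
  invisible(mtx_path)
}
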