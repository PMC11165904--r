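#' Read an observation-by-feature matrix from delimited text or Matrix Market
#'
#' Delimited files (TSV/CSV) may carry an optional header row and an optional
#' leading identifier column; both are auto-detected by one rule: a first row
#' (first column) is treated as header (identifiers) when any of its cells
#' fails to parse as a number. Matrix Market files are read as sparse
#' coordinate triplets.
#'
#' Sparse single-cell matrices are conventionally stored genes x cells; pass
#' `observations = "columns"` to transpose such a file to the internal
#' cells x genes orientation.
#'
#' @param path path to the file.
#' @param format `"auto"` (from the extension: `.mtx`, `.csv`, else TSV),
#'   `"tsv"`, `"csv"` or `"mtx"`.
#' @param observations `"rows"` (default) if rows are observations as stored,
#'   `"columns"` to transpose after reading.
#' @return a numeric matrix (dense for delimited input, `dgCMatrix` for
#'   Matrix Market) with any detected identifiers as dimnames.
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        observations = c("rows", "columns")) {
  format <- match.arg(format)
  observations <- match.arg(observations)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  X <- if (format == "mtx") read_mtx_file(path) else {
    read_delimited_file(path, sep = if (format == "csv") "," else "\t")
  }
  if (observations == "columns") {
    X <- if (inherits(X, "Matrix")) Matrix::t(X) else t(X)
  }
  X
}

read_delimited_file <- function(path, sep) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("%s: file is empty", path), call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad, widths[bad], widths[1L]), call. = FALSE)
  }
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x))) | trimws(x) == "NA"
  header <- !all(is_num(cells[[1L]][-1L])) || !is_num(cells[[1L]][widths[1L]])
  col_ids <- NULL
  if (header) {
    col_ids <- cells[[1L]]
    cells <- cells[-1L]
    if (length(cells) == 0L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  first_col <- vapply(cells, `[[`, "", 1L)
  id_col <- !all(is_num(first_col))
  row_ids <- NULL
  if (id_col) {
    row_ids <- first_col
    cells <- lapply(cells, `[`, -1L)
    # a header over an id column may or may not include a corner cell
    if (!is.null(col_ids) && length(col_ids) == length(cells[[1L]]) + 1L) {
      col_ids <- col_ids[-1L]
    }
  }
  vals <- suppressWarnings(lapply(cells, as.numeric))
  bad_row <- which(vapply(vals, anyNA, logical(1L)))
  if (length(bad_row) > 0L) {
    line_no <- bad_row[1L] + as.integer(header)
    stop(sprintf("%s: non-numeric cell at line %d", path, line_no), call. = FALSE)
  }
  X <- do.call(rbind, vals)
  rownames(X) <- row_ids
  if (!is.null(col_ids) && length(col_ids) == ncol(X)) colnames(X) <- col_ids
  X
}

read_mtx_file <- function(path) {
  X <- tryCatch(Matrix::readMM(path),
                error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                         call. = FALSE))
  methods::as(X, "CsparseMatrix")
}

#' Write a matrix to delimited text or Matrix Market
#'
#' Delimited output carries no header or identifier column unless the matrix
#' has dimnames, and floats are written with 17 significant digits so a
#' read/write round trip is value-identical. Sparse matrices written as
#' `.mtx` use the standard `coordinate real general` dialect.
#'
#' @param X numeric matrix, dense or sparse.
#' @param path output path; extension `.mtx` selects Matrix Market when
#'   `format = "auto"`.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @return the path, invisibly.
#' @export
write_matrix <- function(X, path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", "tsv")
  }
  if (NROW(X) < 1L || NCOL(X) < 1L) {
    stop("refusing to write an empty matrix (zero rows or columns)", call. = FALSE)
  }
  if (format == "mtx") {
    Xs <- if (inherits(X, "sparseMatrix")) X else Matrix::Matrix(as.matrix(X), sparse = TRUE)
    Matrix::writeMM(methods::as(Xs, "CsparseMatrix"), path)
    return(invisible(path))
  }
  Xd <- as.matrix(X)
  sep <- if (format == "csv") "," else "\t"
  fmt_row <- function(v) paste(sprintf("%.17g", v), collapse = sep)
  lines <- apply(Xd, 1L, fmt_row)
  if (!is.null(rownames(Xd))) lines <- paste(rownames(Xd), lines, sep = sep)
  if (!is.null(colnames(Xd))) {
    hdr <- paste(colnames(Xd), collapse = sep)
    if (!is.null(rownames(Xd))) hdr <- paste("id", hdr, sep = sep)
    lines <- c(hdr, lines)
  }
  writeLines(lines, path)
  invisible(path)
}
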