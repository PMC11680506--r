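# Counts are stored as a dense base matrix (cells x genes) with a scale
# attribute; MERFISH panels are a few hundred genes so density is cheap.

new_counts_matrix <- function(mat, scale = c("raw", "volume_normalized")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (any(mat < 0)) stop("counts matrix contains negative values", call. = FALSE)
  if (anyDuplicated(colnames(mat)) > 0) {
    stop("gene names must be unique", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat)) > 0) {
    stop("cell ids must be unique", call. = FALSE)
  }
  attr(mat, "scale") <- scale
  class(mat) <- c("counts_matrix", class(mat))
  mat
}

#' Scale flag of a counts matrix
#'
#' @param x A counts matrix from [read_counts()] or [simulate_tissue()].
#' @return `"raw"` or `"volume_normalized"`.
#' @export
counts_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "raw" else sc
}

#' Read a cell-by-gene counts matrix
#'
#' Supports two plain-text layouts: a dense delimited matrix whose first
#' column holds cell ids and whose header holds gene names, or a
#' MatrixMarket coordinate file with sidecar gene and cell name lists
#' (one name per line; matrix rows = cells unless there are exactly as
#' many rows as genes, in which case it is transposed).
#'
#' @param path Path to the matrix file.
#' @param format `"auto"` (by extension), `"delimited"`, or
#'   `"matrix_market"`.
#' @param genes_path,cells_path Name-list sidecars, required for
#'   MatrixMarket input.
#' @param delim Delimiter for dense input; inferred from the extension
#'   when `NULL`.
#' @return A `counts_matrix` (cells x genes) with scale `"raw"`.
#' @export
read_counts <- function(path, format = c("auto", "delimited", "matrix_market"),
                        genes_path = NULL, cells_path = NULL, delim = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
      "matrix_market"
    } else {
      "delimited"
    }
  }
  if (format == "delimited") {
    if (is.null(delim)) {
      delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    }
    df <- readr::read_delim(path, delim = delim, comment = "#",
                            show_col_types = FALSE, progress = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    if (anyNA(mat)) stop("counts matrix contains non-numeric entries",
                         call. = FALSE)
    rownames(mat) <- as.character(df[[1]])
  } else {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop("matrix_market input requires `genes_path` and `cells_path`",
           call. = FALSE)
    }
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e), call. = FALSE))
    genes <- readLines(genes_path, encoding = "UTF-8")
    cells <- readLines(cells_path, encoding = "UTF-8")
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      mat <- as.matrix(m)
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      mat <- t(as.matrix(m))
    } else {
      stop("MatrixMarket dimensions (", nrow(m), " x ", ncol(m),
           ") do not match name lists (", length(cells), " cells, ",
           length(genes), " genes)", call. = FALSE)
    }
    rownames(mat) <- cells
    colnames(mat) <- genes
  }
  new_counts_matrix(mat, scale = "raw")
}

#' @export
`[.counts_matrix` <- function(x, i, j, ..., drop = TRUE) {
  sc <- counts_scale(x)
  y <- NextMethod(drop = drop)
  if (is.matrix(y)) {
    attr(y, "scale") <- sc
    class(y) <- unique(c("counts_matrix", class(y)))
  }
  y
}

# Align a counts matrix with a cell table; errors name the missing cells.
counts_for_cells <- function(counts, cells) {
  missing <- setdiff(cells$cell_id, rownames(counts))
  if (length(missing) > 0) {
    stop("cell(s) missing from counts matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  }
  counts[cells$cell_id, , drop = FALSE]
}
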