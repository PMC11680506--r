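#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Canonical per-cell fields. Mandatory fields must resolve in the input;
# optional fields are carried when present.
.mandatory_fields <- c("cell_id", "sample_id", "condition", "region",
                       "x", "y", "volume", "cell_type")
.optional_fields  <- c("cell_subtype", "doublet_score", "total_counts")

# Default source-column candidates per canonical field; the first candidate
# present in the file wins. Vendor exports differ, hence the aliases.
default_column_map <- function() {
  list(
    cell_id       = c("cell_id", "cell"),
    sample_id     = c("sample_id", "sample"),
    condition     = "condition",
    region        = "region",
    x             = c("x", "center_x"),
    y             = c("y", "center_y"),
    volume        = "volume",
    cell_type     = "cell_type",
    cell_subtype  = "cell_subtype",
    doublet_score = "doublet_score",
    total_counts  = "total_counts"
  )
}

#' Default condition label mapping
#'
#' Input condition labels are normalized to the two internal levels
#' `reference` and `treatment`, which fixes the sign convention of the
#' differential-proximity effect (positive = higher local proportion in
#' the treatment condition). The default maps normoxia (`NX`) to
#' `reference` and chronic hypoxia (`HX`) to `treatment`; already
#' normalized labels pass through.
#'
#' @return Named character vector mapping input labels to internal levels.
#' @export
default_condition_map <- function() {
  c(NX = "reference", HX = "treatment",
    reference = "reference", treatment = "treatment")
}

new_cell_table <- function(df, provenance = list()) {
  stopifnot(is.data.frame(df))
  out <- as_tibble(df)
  attr(out, "provenance") <- provenance
  class(out) <- unique(c("cell_table", class(out)))
  out
}

#' Validate an in-memory per-cell table
#'
#' Checks the per-cell invariants (finite coordinates, positive volume,
#' unique cell ids, doublet scores in \[0, 1\], at most two condition
#' levels) and returns a normalized `cell_table` tibble. Rows that fail a
#' row-level invariant are dropped and reported in the `rejected`
#' attribute; violations of table-level invariants (missing columns,
#' more than two condition levels) are errors.
#'
#' @param df Data frame with at least the mandatory columns `cell_id`,
#'   `sample_id`, `condition`, `region`, `x`, `y`, `volume`, `cell_type`.
#' @param condition_map Named character vector mapping raw condition
#'   labels to `reference`/`treatment`; see [default_condition_map()].
#' @param provenance Optional list recording the table's origin.
#' @return A `cell_table` tibble with attributes `rejected` (per-row
#'   rejection report) and `provenance`.
#' @export
validate_cell_table <- function(df, condition_map = default_condition_map(),
                                provenance = list()) {
  missing <- setdiff(.mandatory_fields, names(df))
  if (length(missing) > 0) {
    stop("mandatory column(s) missing from cell table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as_tibble(df)
  df$cell_id   <- as.character(df$cell_id)
  df$sample_id <- as.character(df$sample_id)
  df$region    <- as.character(df$region)
  df$cell_type <- as.character(df$cell_type)
  for (col in c("x", "y", "volume")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (!"cell_subtype" %in% names(df)) df$cell_subtype <- df$cell_type
  df$cell_subtype <- as.character(df$cell_subtype)
  if (!"doublet_score" %in% names(df)) df$doublet_score <- NA_real_
  df$doublet_score <- suppressWarnings(as.numeric(df$doublet_score))
  if ("total_counts" %in% names(df)) {
    df$total_counts <- suppressWarnings(as.numeric(df$total_counts))
  }

  raw_cond <- as.character(df$condition)
  mapped <- unname(condition_map[raw_cond])
  known <- !is.na(mapped)

  reasons <- character(nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reasons[bad & !nzchar(reasons)] <<- why
  }
  flag(!known, "unmapped condition label")
  flag(!is.finite(df$x) | !is.finite(df$y), "non-finite coordinate")
  flag(!is.finite(df$volume) | df$volume <= 0, "volume not a positive number")
  flag(!is.na(df$doublet_score) &
         (df$doublet_score < 0 | df$doublet_score > 1),
       "doublet score outside [0, 1]")
  flag(duplicated(df$cell_id), "duplicate cell_id")

  rejected <- tibble(
    row = which(nzchar(reasons)),
    cell_id = df$cell_id[nzchar(reasons)],
    reason = reasons[nzchar(reasons)]
  )
  keep <- !nzchar(reasons)
  df <- df[keep, , drop = FALSE]
  df$condition <- factor(mapped[keep], levels = c("reference", "treatment"))

  lv <- unique(raw_cond[keep])
  if (length(unique(df$condition[!is.na(df$condition)])) > 2 || length(lv) > 2) {
    stop("condition must have exactly two levels; found: ",
         paste(lv, collapse = ", "), call. = FALSE)
  }
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " row(s) rejected during cell-table validation")
  }
  out <- new_cell_table(df, provenance = provenance)
  attr(out, "rejected") <- rejected
  out
}

#' Read a per-cell table from delimited text
#'
#' Reads a CSV/TSV export of segmented cells (one row per cell: sample,
#' condition, region, centroid coordinates in micrometers, volume in
#' cubic micrometers, type labels, optional doublet score), maps its
#' columns onto the canonical field names, normalizes the condition
#' labels, and validates every row. Lines starting with `#` are treated
#' as metadata comments.
#'
#' @param path Path to a delimited text file with a header row (UTF-8).
#' @param delim Field delimiter; `NULL` (default) infers `"\t"` for
#'   `.tsv` files and `","` otherwise.
#' @param column_map Named list or character vector mapping canonical
#'   field names (`cell_id`, `sample_id`, `condition`, `region`, `x`,
#'   `y`, `volume`, `cell_type`, `cell_subtype`, `doublet_score`,
#'   `total_counts`) to source column names. Unspecified fields fall
#'   back to the documented defaults.
#' @param condition_map See [default_condition_map()].
#' @return A validated `cell_table` tibble; rejected rows are reported
#'   in the `rejected` attribute.
#' @export
read_cell_table <- function(path, delim = NULL,
                            column_map = NULL,
                            condition_map = default_condition_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  cmap <- default_column_map()
  if (!is.null(column_map)) {
    for (nm in names(column_map)) cmap[[nm]] <- column_map[[nm]]
  }
  resolved <- list()
  for (field in c(.mandatory_fields, .optional_fields)) {
    hit <- intersect(cmap[[field]], names(raw))
    if (length(hit) > 0) resolved[[field]] <- hit[[1]]
  }
  missing <- setdiff(.mandatory_fields, names(resolved))
  if (length(missing) > 0) {
    stop("mandatory column(s) not found in ", basename(path), ": ",
         paste(missing, collapse = ", "),
         " (adjust `column_map` if they are named differently)",
         call. = FALSE)
  }
  df <- raw[, unlist(resolved), drop = FALSE]
  names(df) <- names(resolved)
  validate_cell_table(df, condition_map = condition_map,
                      provenance = list(source = path, filters = character()))
}

#' Write a tabular result to CSV
#'
#' Writes any result tibble (including a `cell_table`) as UTF-8 CSV with
#' one metadata comment line (`# cellprox <version>`) that
#' [read_cell_table()] and [read_counts()] tolerate. Cell tables
#' round-trip losslessly.
#'
#' @param x Data frame to write.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  con <- tryCatch(file(path, open = "wb", encoding = "UTF-8"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  writeLines(paste0("# cellprox ",
                    as.character(utils::packageVersion("cellprox"))),
             con, useBytes = TRUE)
  close(con)
  readr::write_csv(as.data.frame(x), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x), " cells, ",
      length(unique(x$sample_id)), " sample(s), ",
      length(unique(x$region)), " region(s)\n", sep = "")
  NextMethod()
}
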