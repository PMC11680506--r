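#' Quality-control configuration
#'
#' Thresholds for the five-stage cell-level QC cascade applied to
#' segmented imaging-based spatial transcriptomics data. All boundary
#' comparisons are strict: cells sitting exactly on a threshold
#' (volume = `min_volume`, volume = `max_volume_multiplier` x median,
#' doublet score = `doublet_threshold`, total counts equal to a
#' quantile) are kept.
#'
#' @param min_volume Minimum cell volume in cubic micrometers
#'   (default 50); cells strictly below are removed as segmentation
#'   fragments.
#' @param max_volume_multiplier Cells with volume strictly larger than
#'   this multiple of the median volume of all input cells are removed
#'   (default 3).
#' @param quantile_low,quantile_high Per-cell total-count quantile band
#'   (defaults 0.02 and 0.98, type-7 empirical quantiles); cells
#'   strictly outside are removed.
#' @param doublet_threshold Cells with a doublet score strictly greater
#'   than this are removed (default 0.20); cells without a score pass
#'   and are counted separately.
#' @param normalization_scale Multiplier applied after dividing counts
#'   by cell volume (default 1000).
#' @param quantile_scope `"per_sample"` (default; each tissue run is its
#'   own distribution) or `"pooled"`.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_volume = 50, max_volume_multiplier = 3,
                      quantile_low = 0.02, quantile_high = 0.98,
                      doublet_threshold = 0.20, normalization_scale = 1000,
                      quantile_scope = c("per_sample", "pooled")) {
  quantile_scope <- match.arg(quantile_scope)
  stopifnot(min_volume > 0, max_volume_multiplier > 1,
            quantile_low >= 0, quantile_high <= 1,
            quantile_low < quantile_high,
            normalization_scale > 0,
            doublet_threshold >= 0)
  structure(list(min_volume = min_volume,
                 max_volume_multiplier = max_volume_multiplier,
                 quantile_low = quantile_low, quantile_high = quantile_high,
                 doublet_threshold = doublet_threshold,
                 normalization_scale = normalization_scale,
                 quantile_scope = quantile_scope),
            class = "qc_config")
}

#' Volume filter (QC stage 1)
#'
#' Removes cells with volume strictly below `min_volume` or strictly
#' above `max_volume_multiplier` times the median volume of the cells
#' entering this stage (the median is computed on the whole unfiltered
#' input table, not per sample).
#'
#' @param cells A cell table.
#' @param cfg A [qc_config()].
#' @return List with `cells` (survivors) and `removed_ids`.
#' @export
filter_by_volume <- function(cells, cfg = qc_config()) {
  if (nrow(cells) == 0) {
    warning("empty cell table passed to volume filter")
    return(list(cells = cells, removed_ids = character()))
  }
  med <- stats::median(cells$volume)
  keep <- cells$volume >= cfg$min_volume &
    cells$volume <= cfg$max_volume_multiplier * med
  list(cells = cells[keep, , drop = FALSE],
       removed_ids = cells$cell_id[!keep])
}

#' Zero-count removal (QC stage 2)
#'
#' Removes cells whose total raw transcript count is zero.
#'
#' @inheritParams filter_by_volume
#' @param counts Raw counts matrix covering every cell in `cells`.
#' @return List with `cells` and `removed_ids`.
#' @export
drop_zero_count_cells <- function(cells, counts) {
  if (counts_scale(counts) != "raw") {
    stop("zero-count removal must run on raw counts", call. = FALSE)
  }
  m <- counts_for_cells(counts, cells)
  totals <- rowSums(m)
  keep <- totals > 0
  if (!any(keep) && nrow(cells) > 0) warning("all cells have zero counts")
  list(cells = cells[keep, , drop = FALSE],
       removed_ids = cells$cell_id[!keep])
}

#' Volume normalization (QC stage 3)
#'
#' Divides each cell's counts by its physical volume and multiplies by
#' `normalization_scale` (default 1000), compensating for partial soma
#' capture in thin sections. Refuses to run twice.
#'
#' @inheritParams drop_zero_count_cells
#' @param cfg A [qc_config()].
#' @return A `counts_matrix` with scale `"volume_normalized"`, restricted
#'   to the cells in `cells`.
#' @export
normalize_by_volume <- function(counts, cells, cfg = qc_config()) {
  if (counts_scale(counts) == "volume_normalized") {
    stop("counts are already volume-normalized", call. = FALSE)
  }
  m <- counts_for_cells(counts, cells)
  m <- unclass(m)
  attr(m, "scale") <- NULL
  m <- m / cells$volume[match(rownames(m), cells$cell_id)] *
    cfg$normalization_scale
  new_counts_matrix(m, scale = "volume_normalized")
}

#' Total-count quantile filter (QC stage 4)
#'
#' Removes cells whose per-cell total counts fall strictly below the
#' `quantile_low` quantile or strictly above the `quantile_high`
#' quantile of the totals of the cells entering this stage (type-7
#' empirical quantiles). By default the band is computed per sample;
#' set `quantile_scope = "pooled"` in the config to pool samples.
#'
#' @inheritParams normalize_by_volume
#' @return List with `cells` and `removed_ids`.
#' @export
filter_by_total_count_quantiles <- function(cells, counts, cfg = qc_config()) {
  m <- counts_for_cells(counts, cells)
  totals <- rowSums(m)
  groups <- if (cfg$quantile_scope == "per_sample") {
    cells$sample_id
  } else {
    rep("pooled", nrow(cells))
  }
  keep <- rep(TRUE, nrow(cells))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      warning("fewer than 2 cells in quantile scope '", g,
              "'; no quantile filtering applied there")
      next
    }
    qs <- stats::quantile(totals[idx],
                          probs = c(cfg$quantile_low, cfg$quantile_high),
                          type = 7, names = FALSE)
    keep[idx] <- totals[idx] >= qs[1] & totals[idx] <= qs[2]
  }
  list(cells = cells[keep, , drop = FALSE],
       removed_ids = cells$cell_id[!keep])
}

#' Doublet filter (QC stage 5)
#'
#' Removes cells whose doublet score is strictly greater than the
#' threshold. Cells without a score are kept (score computation is
#' upstream of this package) and their number is reported.
#'
#' @inheritParams filter_by_volume
#' @return List with `cells`, `removed_ids`, and `n_missing_score`.
#' @export
filter_doublets <- function(cells, cfg = qc_config()) {
  ds <- cells$doublet_score
  n_missing <- sum(is.na(ds))
  if (n_missing == nrow(cells) && nrow(cells) > 0) {
    warning("no cell has a doublet score; doublet filter is a no-op")
  }
  drop <- !is.na(ds) & ds > cfg$doublet_threshold
  list(cells = cells[!drop, , drop = FALSE],
       removed_ids = cells$cell_id[drop],
       n_missing_score = n_missing)
}

#' Run the full QC cascade
#'
#' Applies the five stages in order: (1) volume filter, (2) zero-count
#' removal, (3) volume normalization of the counts, (4) total-count
#' quantile filter on the normalized totals, (5) doublet-score filter.
#' The per-stage report telescopes: each stage's survivors are the next
#' stage's input.
#'
#' @inheritParams drop_zero_count_cells
#' @param cfg A [qc_config()].
#' @return List with `cells` (surviving `cell_table`), `counts`
#'   (volume-normalized matrix restricted to survivors), and `report`
#'   (a `qc_report` tibble with columns stage, n_in, n_removed, n_out).
#' @export
run_qc <- function(cells, counts, cfg = qc_config()) {
  if (counts_scale(counts) != "raw") {
    stop("run_qc expects raw counts", call. = FALSE)
  }
  stages <- list()
  note <- function(stage, n_in, n_removed) {
    stages[[length(stages) + 1]] <<- tibble(
      stage = stage, n_in = n_in, n_removed = n_removed,
      n_out = n_in - n_removed)
  }

  s1 <- filter_by_volume(cells, cfg)
  note("volume", nrow(cells), length(s1$removed_ids))

  s2 <- drop_zero_count_cells(s1$cells, counts)
  note("zero_counts", nrow(s1$cells), length(s2$removed_ids))

  norm <- normalize_by_volume(counts, s2$cells, cfg)
  note("volume_normalization", nrow(s2$cells), 0L)

  s4 <- filter_by_total_count_quantiles(s2$cells, norm, cfg)
  note("total_count_quantiles", nrow(s2$cells), length(s4$removed_ids))

  s5 <- filter_doublets(s4$cells, cfg)
  note("doublet_score", nrow(s4$cells), length(s5$removed_ids))

  report <- dplyr::bind_rows(stages)
  attr(report, "quantile_scope") <- cfg$quantile_scope
  attr(report, "n_missing_doublet_score") <- s5$n_missing_score
  attr(report, "note") <- paste(
    "stages applied in order volume -> zero_counts ->",
    "volume_normalization -> total_count_quantiles -> doublet_score;",
    "re-applying the quantile stage to its own survivors can remove",
    "additional cells because the quantile band is re-estimated")
  class(report) <- c("qc_report", class(report))

  out_cells <- s5$cells
  prov <- attr(out_cells, "provenance")
  prov$filters <- c(prov$filters, report$stage)
  out_cells <- new_cell_table(out_cells, provenance = prov)
  out_counts <- norm[out_cells$cell_id, , drop = FALSE]
  if ("total_counts" %in% names(out_cells)) {
    out_cells$total_counts <- rowSums(out_counts)
  }
  list(cells = out_cells, counts = out_counts, report = report)
}
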