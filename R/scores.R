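#' Bundled cell-state score definitions
#'
#' Four curated gene signatures ship with the package: `ol_genesis`
#' (cells primed for oligodendrocyte differentiation), `ol_maturation`
#' (mature oligodendrocytes), `reactive_astrocyte`, and
#' `reactive_microglia`. Gene lists are deduplicated at load time (the
#' curated reactive-microglia list carries `Cst7` twice; it is stored
#' once and the duplication noted).
#'
#' @return Named list of `state_score_definition` objects, each with
#'   `name`, `genes` (unique), `description`, and `note`.
#' @export
state_score_definitions <- function() {
  path <- system.file("extdata", "state_scores.yaml", package = "cellprox",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(def, name) {
    genes <- as.character(def$genes)
    dup <- unique(genes[duplicated(genes)])
    structure(list(name = name,
                   genes = unique(genes),
                   description = def$description,
                   note = if (length(dup) > 0) {
                     paste("duplicated in curated list, stored once:",
                           paste(dup, collapse = ", "))
                   } else {
                     NA_character_
                   }),
              class = "state_score_definition")
  })
}

#' Genes of a bundled score definition
#'
#' @param name One of `"ol_genesis"`, `"ol_maturation"`,
#'   `"reactive_astrocyte"`, `"reactive_microglia"`.
#' @return Character vector of unique gene symbols.
#' @export
state_score_genes <- function(name) {
  defs <- state_score_definitions()
  if (!name %in% names(defs)) {
    stop("unknown score definition: ", name, "; available: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  }
  defs[[name]]$genes
}

#' Per-cell gene-set state score
#'
#' For each gene in the list, expression is z-scored across all cells in
#' the scoring population (both conditions pooled, sample standard
#' deviation, ddof = 1); each cell's score is the mean z-score over the
#' list's genes present in the matrix. Genes with zero variance
#' contribute 0. Gene matching is case-sensitive with a case-insensitive
#' fallback (on by default) for typesetting artifacts in curated lists.
#' By construction the scores average to 0 over the scoring population.
#'
#' @param counts A (typically volume-normalized) counts matrix; rows are
#'   the scoring population.
#' @param genes Character vector of gene symbols, or a
#'   `state_score_definition`.
#' @param cells Optional cell table restricting the scoring population
#'   to its `cell_id`s.
#' @param case_insensitive Fall back to case-insensitive gene matching
#'   (default `TRUE`).
#' @return Tibble with `cell_id` and `score`; attributes `genes_used`
#'   and `genes_missing`.
#' @export
compute_state_score <- function(counts, genes, cells = NULL,
                                case_insensitive = TRUE) {
  if (inherits(genes, "state_score_definition")) genes <- genes$genes
  genes <- unique(as.character(genes))
  m <- if (is.null(cells)) counts else counts_for_cells(counts, cells)
  if (nrow(m) < 2) stop("need at least 2 cells to z-score", call. = FALSE)
  hit <- match(genes, colnames(m))
  if (case_insensitive && anyNA(hit)) {
    fallback <- match(tolower(genes[is.na(hit)]), tolower(colnames(m)))
    if (any(!is.na(fallback))) {
      message("case-insensitive gene match: ",
              paste(genes[is.na(hit)][!is.na(fallback)], collapse = ", "))
    }
    hit[is.na(hit)] <- fallback
  }
  missing <- genes[is.na(hit)]
  used <- colnames(m)[hit[!is.na(hit)]]
  if (length(used) == 0) {
    stop("none of the listed genes is present in the counts matrix",
         call. = FALSE)
  }
  sub <- m[, used, drop = FALSE]
  mu <- colMeans(sub)
  sd <- apply(sub, 2, stats::sd)           # ddof = 1
  z <- sweep(sub, 2, mu, "-")
  pos <- sd > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, sd[pos], "/")
  z[, !pos] <- 0
  out <- tibble(cell_id = rownames(m), score = as.numeric(rowMeans(z)))
  attr(out, "genes_used") <- used
  attr(out, "genes_missing") <- missing
  if (length(missing) > 0) {
    message("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  out
}

#' Replicate-level group means and condition tests for state scores
#'
#' Averages per-cell scores within (sample, region, cell group), then
#' compares the two conditions per (region, group) with the unpaired,
#' two-tailed Student's t test across replicate means -- the test's n is
#' the number of biological replicates, never the number of cells.
#'
#' @param scores Output of [compute_state_score()].
#' @param cells Cell table supplying `sample_id`, `condition`, `region`,
#'   and the grouping column for every scored cell.
#' @param group Grouping column (default `"cell_type"`).
#' @return List with `group_means` (one row per sample x region x group)
#'   and `tests` (one row per region x group with both conditions
#'   represented by at least 2 replicates; degenerate zero-variance
#'   comparisons are flagged in `note`).
#' @export
score_group_means_and_test <- function(scores, cells, group = "cell_type") {
  stopifnot(group %in% names(cells))
  joined <- dplyr::inner_join(
    scores,
    cells[, c("cell_id", "sample_id", "condition", "region", group)],
    by = "cell_id")
  group_means <- joined %>%
    dplyr::group_by(.data$sample_id, .data$condition, .data$region,
                    group = .data[[group]]) %>%
    dplyr::summarise(mean_score = mean(.data$score),
                     n_cells = dplyr::n(), .groups = "drop")
  tests <- group_means %>%
    dplyr::group_by(.data$region, .data$group) %>%
    dplyr::group_modify(function(d, key) {
      ref <- d$mean_score[d$condition == "reference"]
      trt <- d$mean_score[d$condition == "treatment"]
      if (length(ref) < 2 || length(trt) < 2) return(tibble())
      tt <- suppressWarnings(pooled_ttest(ref, trt))
      tibble(mean_ref = mean(ref), mean_trt = mean(trt),
             t = tt$t, df = tt$df, p = tt$p,
             n_ref = length(ref), n_trt = length(trt),
             note = if (tt$p %in% c(0, 1) && mean(ref) != mean(trt) &&
                        is.infinite(tt$t)) {
               "zero variance across replicates"
             } else {
               NA_character_
             })
    }) %>%
    dplyr::ungroup()
  list(group_means = group_means, tests = tests)
}
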