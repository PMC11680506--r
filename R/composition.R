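#' Cell-type proportions per sample and region
#'
#' For each biological replicate and region, the number of cells in each
#' cell subtype divided by either the total number of cells in the
#' region (`region_total`) or the total number of cells of the subtype's
#' broad class in that region (`broad_class`).
#'
#' @param cells A cell table.
#' @param denominator `"region_total"` (default) or `"broad_class"`.
#' @param group Grouping column for the numerator (default
#'   `"cell_subtype"`).
#' @return Tibble with one row per (sample, region, group): `numerator`,
#'   `denominator`, `proportion`, `denominator_kind`.
#' @export
compute_proportions <- function(cells,
                                denominator = c("region_total", "broad_class"),
                                group = "cell_subtype") {
  denominator <- match.arg(denominator)
  stopifnot(group %in% names(cells))
  denom_keys <- c("sample_id", "condition", "region",
                  if (denominator == "broad_class") "cell_type")
  num <- cells %>%
    dplyr::count(dplyr::across(dplyr::all_of(c(denom_keys, group))),
                 name = "numerator")
  den <- cells %>%
    dplyr::count(dplyr::across(dplyr::all_of(denom_keys)),
                 name = "denominator")
  out <- dplyr::inner_join(num, den, by = denom_keys) %>%
    dplyr::rename(group = dplyr::all_of(group)) %>%
    dplyr::mutate(proportion = .data$numerator / .data$denominator,
                  denominator_kind = denominator)
  zero <- out$denominator == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) skipped: zero denominator")
    out <- out[!zero, , drop = FALSE]
  }
  out
}

# Pooled-variance two-sample t test with explicit degenerate branches.
pooled_ttest <- function(ref, trt) {
  n1 <- length(ref); n2 <- length(trt)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(ref) + (n2 - 1) * stats::var(trt)) /
    (n1 + n2 - 2)
  dm <- mean(ref) - mean(trt)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    warning("zero pooled variance with unequal means; p set to 0")
    return(list(t = sign(dm) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sample proportion t test
#'
#' Unpaired, two-tailed Student's t test (pooled variance) comparing the
#' per-replicate proportions of the two conditions, as used for
#' replicate-level (n = 3 vs 3) composition comparisons. The statistic
#' is `(mean_ref - mean_trt) / se`; the percent change is relative to
#' the reference mean.
#'
#' @param ref,trt Numeric vectors of per-replicate proportions (length
#'   at least 2 each).
#' @return Tibble with `t`, `df`, `p`, `mean_ref`, `mean_trt`,
#'   `percent_change`.
#' @export
proportion_ttest <- function(ref, trt) {
  tt <- pooled_ttest(ref, trt)
  tibble(t = tt$t, df = tt$df, p = tt$p,
         mean_ref = mean(ref), mean_trt = mean(trt),
         percent_change = (mean(trt) - mean(ref)) / mean(ref) * 100)
}

#' Proportion tests for every cell group
#'
#' Convenience wrapper: computes per-replicate proportions with
#' [compute_proportions()] and runs [proportion_ttest()] for every
#' (region, group) with at least two replicates per condition. Groups
#' absent from a replicate contribute a zero proportion.
#'
#' @inheritParams compute_proportions
#' @return Tibble with one row per (region, group): test statistics and
#'   per-condition means.
#' @export
test_proportions <- function(cells,
                             denominator = c("region_total", "broad_class"),
                             group = "cell_subtype") {
  props <- compute_proportions(cells, denominator = denominator, group = group)
  samples <- dplyr::distinct(cells, .data$sample_id, .data$condition)
  props %>%
    dplyr::group_by(.data$region, group = .data$group) %>%
    dplyr::group_modify(function(d, key) {
      full <- dplyr::left_join(samples, d,
                               by = c("sample_id", "condition")) %>%
        dplyr::mutate(proportion = dplyr::coalesce(.data$proportion, 0))
      ref <- full$proportion[full$condition == "reference"]
      trt <- full$proportion[full$condition == "treatment"]
      if (length(ref) < 2 || length(trt) < 2) return(tibble())
      proportion_ttest(ref, trt) %>%
        dplyr::mutate(n_ref = length(ref), n_trt = length(trt))
    }) %>%
    dplyr::ungroup()
}
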