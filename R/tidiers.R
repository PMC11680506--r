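#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-proximity fit
#'
#' One row per (region, center type, surround type) with the condition
#' effect on the `log(b_ratio + offset)` scale, its standard error,
#' Satterthwaite degrees of freedom, p-value, within-region
#' Benjamini-Hochberg FDR, per-condition observation and sample counts,
#' and fit status.
#'
#' @param x A `diff_prox` object from [run_differential_proximity()].
#' @param conf.int Add a Wald confidence interval (t quantile at the
#'   fit's degrees of freedom).
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.diff_prox <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- x$results
  if (conf.int) {
    q <- stats::qt(1 - (1 - conf.level) / 2, out$df)
    out$conf.low <- out$beta - q * out$se
    out$conf.high <- out$beta + q * out$se
  }
  out
}

#' Summarize a differential-proximity fit
#'
#' @param x A `diff_prox` object.
#' @param ... Unused.
#' @return One-row tibble: number of regions, ordered pairs, fits by
#'   status, significant pairs at FDR < 0.05, and skipped (isolated)
#'   center cells.
#' @export
glance.diff_prox <- function(x, ...) {
  res <- x$results
  tibble(
    n_regions = length(unique(res$region)),
    n_pairs = nrow(res),
    n_ok = sum(res$status == "ok"),
    n_singular = sum(res$status == "singular_fit"),
    n_insufficient = sum(res$status == "insufficient_data"),
    n_significant = sum(res$fdr < 0.05, na.rm = TRUE),
    n_skipped_cells = nrow(x$skipped),
    offset = x$spec$offset
  )
}

#' Tidy proximity observations
#'
#' @param x A `proximity_result` from [compute_proximity()].
#' @param ... Unused.
#' @return The observation tibble (one row per center cell x surround
#'   type).
#' @export
tidy.proximity_result <- function(x, ...) {
  x$observations
}
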