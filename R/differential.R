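#' Model specification for differential proximity
#'
#' The differential-proximity model is a Gaussian linear mixed model on
#' the log-transformed B-ratio,
#' `log(b_ratio + offset) ~ condition + (1 | sample_id)`,
#' fit by REML. The condition coefficient `beta` is coded so that a
#' positive value means a higher local proportion of the surround type
#' near the center type in the treatment condition than in the
#' reference. Its p-value is a Wald t test with Satterthwaite
#' denominator degrees of freedom, the standard small-sample choice when
#' only a handful of biological replicates carry the contrast.
#'
#' @param offset Added to the B-ratio before taking the natural log so
#'   that zero ratios remain finite (default 0.001).
#' @param min_samples Minimum number of samples per condition for a fit
#'   (default 2).
#' @param min_cells Minimum number of center cells per condition
#'   (default 10).
#' @return A `model_spec` list.
#' @export
model_spec <- function(offset = 0.001, min_samples = 2, min_cells = 10) {
  stopifnot(offset > 0, min_samples >= 2, min_cells >= 1)
  structure(list(offset = offset, min_samples = min_samples,
                 min_cells = min_cells, log_base = "natural",
                 p_method = "Wald t, Satterthwaite df"),
            class = "model_spec")
}

#' Log-transform a B-ratio
#'
#' Natural log of `b_ratio + offset`; the offset accommodates zero
#' ratios (a center cell with no surround-type neighbor).
#'
#' @param b_ratio Numeric in \[0, 1\].
#' @param offset Positive offset (default 0.001).
#' @return `log(b_ratio + offset)`.
#' @export
transform_response <- function(b_ratio, offset = 0.001) {
  stopifnot(offset > 0)
  if (any(b_ratio < 0 | b_ratio > 1, na.rm = TRUE)) {
    stop("b_ratio must lie in [0, 1]", call. = FALSE)
  }
  log(b_ratio + offset)
}

result_row <- function(obs, status, beta = NA_real_, se = NA_real_,
                       df = NA_real_, p = NA_real_) {
  by_cond <- function(f, lev) {
    v <- obs[obs$condition == lev, , drop = FALSE]
    f(v)
  }
  tibble(
    region = obs$region[1],
    center_type = obs$center_type[1],
    surround_type = obs$surround_type[1],
    beta = beta, se = se, df = df, p = p, fdr = NA_real_,
    n_obs_ref = by_cond(nrow, "reference"),
    n_obs_trt = by_cond(nrow, "treatment"),
    n_samples_ref = by_cond(function(v) length(unique(v$sample_id)), "reference"),
    n_samples_trt = by_cond(function(v) length(unique(v$sample_id)), "treatment"),
    status = status
  )
}

#' Fit the condition effect for one cell-type pair
#'
#' Fits `log(b_ratio + offset) ~ condition + (1 | sample_id)` (Gaussian,
#' REML) to the B-ratio observations of one (region, center type,
#' surround type) stratum. If the random-intercept variance estimate
#' lands exactly on the zero boundary (a singular fit), the model is
#' refit without the random intercept and flagged `singular_fit`.
#' Strata with fewer than `min_samples` samples or `min_cells` center
#' cells in either condition, or with no response variance, are returned
#' as `insufficient_data` with no estimate.
#'
#' @param observations B-ratio observations for a single (region, center
#'   type, surround type): columns `b_ratio`, `condition`, `sample_id`
#'   (plus `region`, `center_type`, `surround_type` carried through).
#' @param spec A [model_spec()].
#' @return One-row tibble: `region`, `center_type`, `surround_type`,
#'   `beta`, `se`, `df`, `p`, `fdr` (filled later), observation and
#'   sample counts per condition, `status`.
#' @export
fit_pair <- function(observations, spec = model_spec()) {
  obs <- observations
  obs$condition <- factor(as.character(obs$condition),
                          levels = c("reference", "treatment"))
  n_cells <- table(factor(obs$condition, levels = c("reference", "treatment")))
  n_samp <- tapply(obs$sample_id, obs$condition,
                   function(s) length(unique(s)))
  n_samp[is.na(n_samp)] <- 0
  y <- transform_response(obs$b_ratio, spec$offset)
  if (any(n_cells < spec$min_cells) || any(n_samp < spec$min_samples) ||
      stats::var(y) == 0) {
    return(result_row(obs, "insufficient_data"))
  }
  dat <- data.frame(y = y, condition = obs$condition,
                    sample_id = factor(obs$sample_id))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ condition + (1 | sample_id), data = dat, REML = TRUE)
  ))
  if (lme4::isSingular(fit, tol = 1e-8)) {
    lmfit <- stats::lm(y ~ condition, data = dat)
    co <- stats::coef(summary(lmfit))["conditiontreatment", ]
    return(result_row(obs, "singular_fit",
                      beta = unname(co["Estimate"]),
                      se = unname(co["Std. Error"]),
                      df = stats::df.residual(lmfit),
                      p = unname(co["Pr(>|t|)"])))
  }
  co <- stats::coef(summary(fit))["conditiontreatment", ]
  result_row(obs, "ok",
             beta = unname(co["Estimate"]),
             se = unname(co["Std. Error"]),
             df = unname(co["df"]),
             p = unname(co["Pr(>|t|)"]))
}

#' Benjamini-Hochberg adjustment within region
#'
#' Fills the `fdr` column of a differential-proximity result table by
#' applying Benjamini-Hochberg within each region across all pairs that
#' produced a p-value (statuses `ok` and `singular_fit`);
#' `insufficient_data` pairs are excluded from the family.
#'
#' @param results Tibble of [fit_pair()] rows.
#' @return The same tibble with `fdr` filled.
#' @export
fdr_adjust <- function(results) {
  results %>%
    dplyr::group_by(.data$region) %>%
    dplyr::mutate(fdr = ifelse(is.na(.data$p), NA_real_,
                               stats::p.adjust(.data$p, method = "BH"))) %>%
    dplyr::ungroup()
}

#' Differential proximity between conditions
#'
#' End-to-end analysis: computes B-ratio observations for every
#' (sample, region) stratum with the data-derived radius, fits the
#' mixed-effects condition model for every ordered (center type,
#' surround type) pair within each region, and controls the false
#' discovery rate per region. The pair matrix is genuinely asymmetric:
#' A near B and B near A are independent tests.
#'
#' @inheritParams compute_proximity
#' @param spec A [model_spec()].
#' @return A `diff_prox` object: list with `results` (one row per
#'   region x ordered type pair), `distance_units`, `skipped`, `spec`,
#'   and `params`. Use [tidy()] / [glance()] / [autoplot()] or
#'   [beta_matrix()] on it.
#' @export
run_differential_proximity <- function(cells,
                                       type_level = c("cell_subtype", "cell_type"),
                                       multiplier = 5, r = NULL,
                                       spec = model_spec()) {
  type_level <- match.arg(type_level)
  prox <- compute_proximity(cells, type_level = type_level,
                            multiplier = multiplier, r = r)
  obs <- prox$observations
  results <- obs %>%
    dplyr::group_by(.data$region, .data$center_type, .data$surround_type) %>%
    dplyr::group_split() %>%
    purrr::map_dfr(fit_pair, spec = spec) %>%
    fdr_adjust()
  structure(list(results = results,
                 distance_units = prox$distance_units,
                 skipped = prox$skipped,
                 spec = spec,
                 params = prox$params),
            class = "diff_prox")
}

#' Per-cell two-sample t test ignoring sample structure
#'
#' Diagnostic comparator for [fit_pair()]: a naive two-sample t test on
#' the transformed per-cell B-ratios that treats every cell as
#' independent. With clustered (multi-sample) data its type-I error is
#' badly inflated; it exists to demonstrate why the mixed model is
#' required, not for inference.
#'
#' @inheritParams fit_pair
#' @return One-row tibble with `estimate` (treatment minus reference
#'   mean of the transformed response) and `p`.
#' @export
fit_pair_naive <- function(observations, spec = model_spec()) {
  y <- transform_response(observations$b_ratio, spec$offset)
  g <- factor(as.character(observations$condition),
              levels = c("reference", "treatment"))
  yr <- y[g == "reference"]
  yt <- y[g == "treatment"]
  if (length(yr) < 2 || length(yt) < 2 || stats::var(y) == 0) {
    return(tibble(estimate = NA_real_, p = NA_real_))
  }
  tt <- stats::t.test(yt, yr, var.equal = TRUE)
  tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
         p = tt$p.value)
}

#' Effect-size matrix for one region
#'
#' Center types as rows, surround types as columns, the condition effect
#' `beta` as value. Pairs without an estimate (insufficient data) are
#' `NA`. The companion significance mask marks pairs with FDR below
#' `alpha`.
#'
#' @param x A `diff_prox` object.
#' @param region Region to export; defaults to the only region present.
#' @param alpha FDR threshold for the significance mask (default 0.05).
#' @return List with `beta` and `significant` matrices.
#' @export
beta_matrix <- function(x, region = NULL, alpha = 0.05) {
  stopifnot(inherits(x, "diff_prox"))
  res <- x$results
  regions <- unique(res$region)
  if (is.null(region)) {
    if (length(regions) > 1) {
      stop("multiple regions present; specify `region`", call. = FALSE)
    }
    region <- regions
  }
  res <- res[res$region == region, ]
  ctypes <- sort(unique(res$center_type))
  stypes <- sort(unique(res$surround_type))
  beta <- matrix(NA_real_, length(ctypes), length(stypes),
                 dimnames = list(center = ctypes, surround = stypes))
  sig <- matrix(FALSE, length(ctypes), length(stypes),
                dimnames = dimnames(beta))
  idx <- cbind(match(res$center_type, ctypes), match(res$surround_type, stypes))
  beta[idx] <- res$beta
  sig[idx] <- !is.na(res$fdr) & res$fdr < alpha
  list(beta = beta, significant = sig)
}

#' @export
print.diff_prox <- function(x, ...) {
  n_sig <- sum(x$results$fdr < 0.05, na.rm = TRUE)
  cat("<diff_prox> ", nrow(x$results), " ordered type pairs across ",
      length(unique(x$results$region)), " region(s); ",
      n_sig, " significant at FDR < 0.05\n", sep = "")
  cat("model: log(b_ratio + ", x$spec$offset,
      ") ~ condition + (1 | sample_id), REML, ", x$spec$p_method, "\n",
      sep = "")
  invisible(x)
}
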