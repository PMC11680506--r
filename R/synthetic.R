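# Synthetic two-condition tissues with known ground truth. Background
# cells follow a homogeneous Poisson process on a rectangle; condition-
# dependent attraction places a fraction of satellite-type cells inside
# a disk around randomly chosen center-type cells; sample-level random
# effects are induced by multiplicative log-normal jitter of the type
# proportions (and of the placement fractions), which is what actually
# moves B-ratio compositions sample to sample.

#' Synthetic tissue configuration
#'
#' Describes a multi-sample, two-condition simulated tissue: domain size,
#' overall cell intensity, cell-type proportions, condition-specific
#' attraction effects, sample-level random effects, per-cell volume and
#' doublet models, and a marker-structured negative-binomial counts
#' model. Defaults echo MERFISH-scale data (about 2,000 cells per
#' 1 x 1 mm sample, median volume about 180 cubic micrometers, roughly
#' 285 transcripts per cell) as realism anchors.
#'
#' @param n_samples Named vector: samples per condition
#'   (default `c(reference = 3, treatment = 3)`).
#' @param width,height Domain rectangle in micrometers (default 1000).
#' @param intensity Expected cells per square micrometer
#'   (default 0.002).
#' @param type_props Named numeric: cell-type proportions summing to 1.
#' @param attraction Optional tibble with columns `center_type`,
#'   `satellite_type`, `f_reference`, `f_treatment`, `radius_mult`: in
#'   each condition, that fraction of satellite-type cells is placed
#'   within `radius_mult` times the expected nearest-neighbor distance
#'   of a center-type cell. Placement is by label exchange with cells
#'   already there (other types backfill the vacated positions), so the
#'   spatial point pattern -- and hence the distance unit d -- is
#'   identical in law across conditions and only the local type
#'   composition differs.
#' @param sample_effect_sd Standard deviation of the log-normal
#'   per-sample jitter applied to type proportions and placement
#'   fractions (default 0.1); set 0 for no sample effects.
#' @param volume_meanlog,volume_sdlog Log-normal volume model (defaults
#'   `log(180)` and 0.4).
#' @param doublet_fraction Fraction of cells flagged as doublets
#'   (default 0.03); doublets draw scores above 0.20, singlets below.
#' @param markers_per_type,marker_mean,marker_background_mean Marker
#'   structure of the counts model: each type has its own markers with
#'   mean `marker_mean` (others see `marker_background_mean`).
#' @param n_shared_genes,shared_mean Shared housekeeping genes.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param score_shift Optional list `(genes, subtype, factor)`: the
#'   negative-binomial means of `genes` are multiplied by `factor` in
#'   cells of `subtype`, creating a known state-score shift.
#' @param region Region label for all cells (default `"sim_region"`).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = c(reference = 3, treatment = 3),
                             width = 1000, height = 1000,
                             intensity = 0.002,
                             type_props = c(Astro = 0.40, Neuron = 0.35,
                                            OPC = 0.25),
                             attraction = NULL,
                             sample_effect_sd = 0.1,
                             volume_meanlog = log(180), volume_sdlog = 0.4,
                             doublet_fraction = 0.03,
                             markers_per_type = 3, marker_mean = 30,
                             marker_background_mean = 0.5,
                             n_shared_genes = 8, shared_mean = 24,
                             nb_size = 2,
                             score_shift = NULL,
                             region = "sim_region") {
  stopifnot(all(c("reference", "treatment") %in% names(n_samples)),
            all(n_samples >= 1),
            width > 0, height > 0, intensity > 0,
            !is.null(names(type_props)), all(type_props > 0),
            sample_effect_sd >= 0, volume_sdlog >= 0,
            doublet_fraction >= 0, doublet_fraction <= 1,
            nb_size > 0)
  if (abs(sum(type_props) - 1) > 1e-8) {
    stop("type_props must sum to 1", call. = FALSE)
  }
  if (width * height * intensity < 2) {
    stop("infeasible intensity: fewer than 2 cells expected per sample",
         call. = FALSE)
  }
  if (!is.null(attraction)) {
    attraction <- as_tibble(attraction)
    needed <- c("center_type", "satellite_type", "f_reference",
                "f_treatment", "radius_mult")
    stopifnot(all(needed %in% names(attraction)),
              all(attraction$f_reference >= 0 & attraction$f_reference <= 1),
              all(attraction$f_treatment >= 0 & attraction$f_treatment <= 1),
              all(attraction$center_type %in% names(type_props)),
              all(attraction$satellite_type %in% names(type_props)))
  }
  structure(list(n_samples = n_samples, width = width, height = height,
                 intensity = intensity, type_props = type_props,
                 attraction = attraction,
                 sample_effect_sd = sample_effect_sd,
                 volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
                 doublet_fraction = doublet_fraction,
                 markers_per_type = markers_per_type,
                 marker_mean = marker_mean,
                 marker_background_mean = marker_background_mean,
                 n_shared_genes = n_shared_genes, shared_mean = shared_mean,
                 nb_size = nb_size, score_shift = score_shift,
                 region = region),
            class = "synthetic_config")
}

# Expected nearest-neighbor distance of a homogeneous Poisson process.
expected_nn_distance <- function(intensity) 0.5 / sqrt(intensity)

# Background process for one sample: homogeneous Poisson positions,
# jittered type proportions, volumes and doublet scores. Attraction is
# applied afterwards (apply_attraction) so that, seed for seed, a null
# and an attraction configuration share every background draw and differ
# only in type labels.
sim_background <- function(cfg, sample_id, condition) {
  n <- stats::rpois(1, cfg$intensity * cfg$width * cfg$height)
  if (n < 2) {
    stop("sample ", sample_id, " realized fewer than 2 cells", call. = FALSE)
  }
  x <- stats::runif(n, 0, cfg$width)
  y <- stats::runif(n, 0, cfg$height)
  props <- cfg$type_props *
    exp(stats::rnorm(length(cfg$type_props), 0, cfg$sample_effect_sd))
  props <- props / sum(props)
  types <- sample(names(props), n, replace = TRUE, prob = props)
  volume <- stats::rlnorm(n, cfg$volume_meanlog, cfg$volume_sdlog)
  is_doublet <- stats::runif(n) < cfg$doublet_fraction
  doublet_score <- ifelse(is_doublet,
                          stats::runif(n, 0.25, 0.95),
                          stats::runif(n, 0, 0.20))
  list(cells = tibble(
         cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
         sample_id = sample_id, condition = condition,
         region = cfg$region, x = x, y = y, volume = volume,
         cell_type = types, cell_subtype = types,
         doublet_score = doublet_score),
       is_doublet = is_doublet, props = props)
}

# Label exchange: a fraction f of satellite-type cells is placed within
# the placement radius of a center-type cell by swapping labels with
# non-center, non-satellite cells already there. The point pattern stays
# homogeneous, so the distance unit d and local densities are identical
# in law across conditions; only the local type composition carries the
# effect.
apply_attraction <- function(cfg, sim) {
  cells <- sim$cells
  types <- cells$cell_type
  xy <- cbind(cells$x, cells$y)
  condition <- cells$condition[1]
  realized_f <- tibble()
  for (i in seq_len(nrow(cfg$attraction))) {
    eff <- cfg$attraction[i, ]
    f <- if (condition == "treatment") eff$f_treatment else eff$f_reference
    f_s <- min(1, f * exp(stats::rnorm(1, 0, cfg$sample_effect_sd)))
    ctr <- which(types == eff$center_type)
    sats <- which(types == eff$satellite_type)
    n_target <- round(f_s * length(sats))
    n_moved <- 0L
    if (n_target > 0 && length(ctr) > 0) {
      rad <- eff$radius_mult * expected_nn_distance(cfg$intensity)
      d_ctr <- RANN::nn2(xy[ctr, , drop = FALSE], xy, k = 1)$nn.dists[, 1]
      in_disk <- d_ctr <= rad
      cand <- which(in_disk &
                      !(types %in% c(eff$center_type, eff$satellite_type)))
      donor <- which(!in_disk & types == eff$satellite_type)
      n_moved <- min(n_target, length(cand), length(donor))
      if (n_moved > 0) {
        to_sat <- sample(cand, n_moved)
        from_sat <- sample(donor, n_moved)
        types[from_sat] <- types[to_sat]
        types[to_sat] <- eff$satellite_type
      }
    }
    realized_f <- dplyr::bind_rows(realized_f, tibble(
      sample_id = cells$sample_id[1], center_type = eff$center_type,
      satellite_type = eff$satellite_type, f_nominal = f_s,
      f_realized = if (length(sats) > 0) n_moved / length(sats) else 0))
  }
  cells$cell_type <- types
  cells$cell_subtype <- types
  sim$cells <- cells
  sim$realized_f <- realized_f
  sim
}

sim_counts <- function(cfg, cells) {
  types <- names(cfg$type_props)
  genes <- c(unlist(lapply(types, function(t) {
    sprintf("%s_mk%d", t, seq_len(cfg$markers_per_type))
  })),
  sprintf("shared_%d", seq_len(cfg$n_shared_genes)))
  mu_tab <- matrix(cfg$marker_background_mean, length(types), length(genes),
                   dimnames = list(types, genes))
  for (t in types) {
    mu_tab[t, sprintf("%s_mk%d", t, seq_len(cfg$markers_per_type))] <-
      cfg$marker_mean
  }
  mu_tab[, grep("^shared_", genes)] <- cfg$shared_mean
  mu <- mu_tab[cells$cell_type, , drop = FALSE]
  if (!is.null(cfg$score_shift)) {
    sel <- cells$cell_subtype == cfg$score_shift$subtype
    gsel <- intersect(cfg$score_shift$genes, genes)
    mu[sel, gsel] <- mu[sel, gsel] * cfg$score_shift$factor
  }
  counts <- matrix(stats::rnbinom(length(mu), size = cfg$nb_size, mu = mu),
                   nrow(mu), ncol(mu),
                   dimnames = list(cells$cell_id, genes))
  storage.mode(counts) <- "double"
  new_counts_matrix(counts, scale = "raw")
}

#' Simulate a multi-sample two-condition tissue
#'
#' Generates cells, counts, and ground truth from a
#' [synthetic_config()]. Fully reproducible: the same configuration and
#' seed give byte-identical outputs.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `cells` (a validated `cell_table`), `counts` (raw
#'   `counts_matrix`), and `truth` (attraction settings, realized
#'   per-sample type proportions and placement fractions, per-cell
#'   doublet flags, score-shift settings).
#' @export
simulate_tissue <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seed, {
    ids <- c(sprintf("ref%d", seq_len(config$n_samples[["reference"]])),
             sprintf("trt%d", seq_len(config$n_samples[["treatment"]])))
    conds <- rep(c("reference", "treatment"), config$n_samples)
    sims <- purrr::map2(ids, conds, function(sid, cond) {
      sim_background(config, sid, cond)
    })
    if (!is.null(config$attraction)) {
      sims <- purrr::map(sims, function(s) apply_attraction(config, s))
    }
    cells_raw <- dplyr::bind_rows(purrr::map(sims, "cells"))
    counts <- sim_counts(config, cells_raw)
    cells_raw$total_counts <- rowSums(counts)
    cells <- validate_cell_table(
      cells_raw, provenance = list(source = "simulate_tissue", seed = seed))
    truth <- list(
      attraction = config$attraction,
      sample_type_props = stats::setNames(purrr::map(sims, "props"), ids),
      realized_f = dplyr::bind_rows(purrr::map(sims, "realized_f")),
      doublet_flags = tibble(
        cell_id = cells_raw$cell_id,
        is_doublet = unlist(purrr::map(sims, "is_doublet"))),
      score_shift = config$score_shift,
      seed = seed)
    list(cells = cells, counts = counts, truth = truth)
  })
}

#' Designed 12-cell QC fixture
#'
#' A hand-designed single-sample table that trips each QC rule exactly
#' once: one cell below the 50 cubic-micrometer volume floor, one with
#' zero counts, one whose normalized total lies strictly above the 98%
#' quantile, and one with doublet score 0.21. Boundary cells (volume
#' exactly 50, volume exactly three times the median, doublet score
#' exactly 0.20) and one unscored cell are included and must survive.
#' The designed part is seed-independent; the seed only jitters the
#' coordinates.
#'
#' @param seed Integer seed for the coordinate jitter.
#' @return List with `cells`, `counts` (raw), and `expected_survivors`
#'   (8 cell ids, enumerated by hand).
#' @export
simulate_qc_fixture <- function(seed = 1) {
  ids <- sprintf("c%02d", 1:12)
  volumes <- c(40, 50, rep(100, 9), 300)
  totals <- c(2, 5, 0, 10, rep(20, 6), 100, 60)
  doublet <- c(0.05, 0.05, 0.05, 0.05, 0.21, 0.20, NA, 0.05, 0.05, 0.05,
               0.05, 0.05)
  counts <- cbind(gA = pmax(totals - 2, 0),
                  gB = as.numeric(totals >= 1),
                  gC = as.numeric(totals >= 2))
  rownames(counts) <- ids
  grid <- expand.grid(x = seq(0, 60, by = 20), y = seq(0, 40, by = 20))[1:12, ]
  xy <- withr::with_seed(seed, {
    cbind(grid$x + stats::runif(12, -1, 1), grid$y + stats::runif(12, -1, 1))
  })
  cells <- validate_cell_table(tibble(
    cell_id = ids, sample_id = "s1", condition = "reference",
    region = "fixture", x = xy[, 1], y = xy[, 2], volume = volumes,
    cell_type = "TypeA", cell_subtype = "TypeA", doublet_score = doublet),
    provenance = list(source = "simulate_qc_fixture"))
  list(cells = cells,
       counts = new_counts_matrix(counts, scale = "raw"),
       expected_survivors = c("c02", "c04", "c06", "c07", "c08", "c09",
                              "c10", "c12"))
}

#' Monte-Carlo ground truth for a synthetic configuration
#'
#' Estimates, for every ordered (center type, surround type) pair, the
#' expected condition difference in the mean of
#' `log(b_ratio + offset)` under a configuration, by simulating
#' `n_reps` tissues and averaging per-sample means within condition.
#' Used as the recovery target for the differential-proximity model.
#'
#' @param config A [synthetic_config()].
#' @param n_reps Number of simulated tissues (default 20).
#' @param seed Integer seed.
#' @param offset Offset of the log transform (default 0.001).
#' @param type_level Type level at which to compute proximity.
#' @return Tibble with one row per ordered pair: `delta` (treatment
#'   minus reference), `se` (Monte-Carlo standard error), `n_reps`.
#' @export
empirical_ground_truth <- function(config, n_reps = 20, seed = 1,
                                   offset = 0.001,
                                   type_level = c("cell_type", "cell_subtype")) {
  type_level <- match.arg(type_level)
  stopifnot(n_reps >= 2)
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, n_reps))
  per_rep <- purrr::map_dfr(seq_len(n_reps), function(i) {
    sim <- simulate_tissue(config, seed = seeds[i])
    prox <- compute_proximity(sim$cells, type_level = type_level)
    prox$observations %>%
      dplyr::group_by(.data$center_type, .data$surround_type,
                      .data$condition, .data$sample_id) %>%
      dplyr::summarise(
        m = mean(transform_response(.data$b_ratio, offset)),
        .groups = "drop") %>%
      dplyr::group_by(.data$center_type, .data$surround_type,
                      .data$condition) %>%
      dplyr::summarise(m = mean(.data$m), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "condition", values_from = "m") %>%
      dplyr::mutate(delta_rep = .data$treatment - .data$reference, rep = i)
  })
  per_rep %>%
    dplyr::group_by(.data$center_type, .data$surround_type) %>%
    dplyr::summarise(delta = mean(.data$delta_rep),
                     se = stats::sd(.data$delta_rep) / sqrt(dplyr::n()),
                     n_reps = dplyr::n(), .groups = "drop")
}

#' Frozen benchmark configurations
#'
#' Two study designs used throughout the package's validation suite.
#' `null_benchmark_config()` is a three-type tissue (40/35/25%) with no
#' attraction and sample-level proportion jitter (sd 0.1) -- about 2,000
#' cells per 1 x 1 mm sample, 3 + 3 samples -- used to check type-I
#' error calibration of the mixed model against sample clustering.
#' `recovery_benchmark_config()` injects one attraction effect: a rare
#' center type (OPC, 8%) around which 40% of a satellite type (Astro,
#' 10%) is placed, calibrated by Monte-Carlo ground truth to a condition
#' difference of about 0.5 in mean `log(b_ratio + 0.001)` for the
#' OPC -> Astro ordered pair. The 1.5 x 1.5 mm domain (about 4,500
#' cells, 360 center cells per sample) and nominal sample jitter sd 0.02
#' (the realized between-sample sd on the log-ratio scale is larger --
#' the zero fraction amplifies proportion jitter -- and is estimated
#' and reported) size the 3 + 3 design for power at that effect size
#' given the large per-cell variance of the log ratio (a design-time
#' power analysis; see the vignette).
#'
#' @return A [synthetic_config()].
#' @export
null_benchmark_config <- function() {
  synthetic_config()
}

#' @rdname null_benchmark_config
#' @export
recovery_benchmark_config <- function() {
  synthetic_config(
    width = 1500, height = 1500,
    type_props = c(Neuron = 0.82, Astro = 0.10, OPC = 0.08),
    sample_effect_sd = 0.02,
    attraction = tibble(center_type = "OPC", satellite_type = "Astro",
                        f_reference = 0, f_treatment = 0.42,
                        radius_mult = 1.5))
}

#' Drop cells within a margin of the domain boundary
#'
#' Fixed-radius statistics are biased near the tissue edge because
#' neighborhoods are truncated. For simulated rectangular domains this
#' helper removes cells within `margin` of the boundary so analyses can
#' be restricted to the interior.
#'
#' @param cells A cell table simulated on `[0, width] x [0, height]`.
#' @param margin Margin width in micrometers (typically the proximity
#'   radius `r`).
#' @param width,height Domain rectangle.
#' @return The cell table restricted to the interior.
#' @export
trim_boundary <- function(cells, margin, width, height) {
  keep <- cells$x >= margin & cells$x <= width - margin &
    cells$y >= margin & cells$y <= height - margin
  cells[keep, , drop = FALSE]
}
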