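# Independent brute-force oracles (plain double loops, no spatial index)
# and small fixture builders shared across the test files.

# O(n^2) nearest-neighbor distances.
oracle_nn_dist <- function(xy) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
      if (dd < best) best <- dd
    }
    out[i] <- best
  }
  out
}

# O(n^2) closed-ball neighbor counts per surround type.
oracle_radius_counts <- function(xy, r, types) {
  n <- nrow(xy)
  lev <- sort(unique(types))
  n_total <- integer(n)
  n_b <- matrix(0L, n, length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
      if (dd <= r) {
        n_total[i] <- n_total[i] + 1L
        n_b[i, types[j]] <- n_b[i, types[j]] + 1L
      }
    }
  }
  list(n_total = n_total, n_b = n_b)
}

# Type-7 quantile by the textbook formula, independent of stats::quantile.
oracle_quantile_type7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
}

# Minimal valid cell table for unit tests.
make_cells <- function(n = 10, sample_id = "s1", condition = "reference",
                       region = "r1", type = "T1", seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    cell_id = sprintf("%s_%03d", sample_id, seq_len(n)),
    sample_id = sample_id, condition = condition, region = region,
    x = stats::runif(n, 0, 100), y = stats::runif(n, 0, 100),
    volume = stats::runif(n, 80, 200),
    cell_type = type, cell_subtype = type,
    doublet_score = stats::runif(n, 0, 0.15)))
}

# Random multi-type stratum used by the proximity oracle tests.
make_typed_stratum <- function(n, seed, types = c("A", "B", "C"),
                               width = 200) {
  withr::with_seed(seed, tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n)),
    sample_id = "s1", condition = "reference", region = "r1",
    x = stats::runif(n, 0, width), y = stats::runif(n, 0, width),
    volume = 150,
    cell_type = sample(types, n, replace = TRUE),
    doublet_score = NA_real_)) |>
    (\(d) {d$cell_subtype <- d$cell_type; d})()
}

# Observations drawn exactly from the Gaussian LMM on the transformed
# scale; b_ratio back-transformed so fit_pair's own transform recovers y.
make_lmm_obs <- function(beta = 0.5, intercept = -2, sample_sd = 0.2,
                         resid_sd = 0.5, n_samples = 3, n_cells = 200,
                         offset = 0.001, seed = 1) {
  withr::with_seed(seed, {
    samp <- c(sprintf("ref%d", seq_len(n_samples)),
              sprintf("trt%d", seq_len(n_samples)))
    cond <- rep(c("reference", "treatment"), each = n_samples)
    b <- stats::rnorm(2 * n_samples, 0, sample_sd)
    do.call(rbind, lapply(seq_along(samp), function(k) {
      y <- intercept + beta * (cond[k] == "treatment") + b[k] +
        stats::rnorm(n_cells, 0, resid_sd)
      y <- pmin(y, log(1 + offset))          # keep b_ratio inside [0, 1]
      tibble::tibble(region = "r1", center_type = "A", surround_type = "B",
                     sample_id = samp[k], condition = cond[k],
                     b_ratio = exp(y) - offset)
    }))
  })
}
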