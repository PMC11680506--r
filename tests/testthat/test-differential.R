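test_that("the response transform is the offset natural log", {
  expect_equal(transform_response(0), log(0.001))
  expect_equal(transform_response(0.999), 0)
  expect_equal(transform_response(0.25, offset = 0.05), log(0.30))
  b <- seq(0, 1, by = 0.1)
  expect_true(all(diff(transform_response(b)) > 0))
  expect_error(transform_response(1.2), "0, 1")
})

test_that("fit_pair recovers a known effect from exact-LMM data", {
  obs <- make_lmm_obs(beta = 0.5, seed = 42)
  res <- fit_pair(obs)
  expect_identical(res$status, "ok")
  expect_equal(res$beta, 0.5, tolerance = 0.5)
  expect_equal(res$n_obs_ref, 600)
  expect_equal(res$n_samples_trt, 3)

  # point estimate is invariant under exact duplication of every row
  # duplication halves only the residual contribution to the standard
  # error; the between-sample component is untouched, so the se cannot grow
  dup <- fit_pair(dplyr::bind_rows(obs, obs))
  expect_equal(dup$beta, res$beta, tolerance = 1e-6)
  expect_lte(dup$se, res$se * 1.0001)
})

test_that("Wald intervals from exact-LMM simulations cover the truth", {
  hits <- vapply(1:100, function(i) {
    obs <- make_lmm_obs(beta = 0.5, seed = 1000 + i)
    r <- fit_pair(obs)
    q <- stats::qt(0.975, r$df)
    r$beta - q * r$se <= 0.5 && 0.5 <= r$beta + q * r$se
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("null LMM data give centered estimates", {
  z <- vapply(1:60, function(i) {
    r <- fit_pair(make_lmm_obs(beta = 0, seed = 2000 + i))
    r$beta / r$se
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.5)
  # the Wald ratio has small-sample (t, df ~ 4) tails, so |z| > 3 occurs
  # in a few percent of null fits even when the model is correct
  expect_gte(mean(abs(z) < 3), 0.93)
})

test_that("insufficient data is flagged instead of fit", {
  obs <- make_lmm_obs(n_cells = 5, seed = 3)
  r <- fit_pair(obs)             # 15 cells per condition but min_cells 10 ok
  expect_identical(r$status, "ok")
  r2 <- fit_pair(obs, model_spec(min_cells = 20))
  expect_identical(r2$status, "insufficient_data")
  expect_true(is.na(r2$beta) && is.na(r2$p))

  one_cond <- obs[obs$condition == "reference", ]
  r3 <- fit_pair(one_cond)
  expect_identical(r3$status, "insufficient_data")

  flat <- obs
  flat$b_ratio <- 0.5
  expect_identical(fit_pair(flat)$status, "insufficient_data")

  two_samples <- obs[obs$sample_id %in% c("ref1", "trt1"), ]
  expect_identical(fit_pair(two_samples)$status, "insufficient_data")
})

test_that("Benjamini-Hochberg matches the hand computation within region", {
  res <- tibble::tibble(
    region = "r1", center_type = letters[1:4], surround_type = "x",
    beta = 1, se = 1, df = 4, p = c(0.01, 0.02, 0.03, 0.04),
    fdr = NA_real_, n_obs_ref = 20, n_obs_trt = 20,
    n_samples_ref = 3, n_samples_trt = 3, status = "ok")
  adj <- fdr_adjust(res)
  expect_equal(adj$fdr, rep(0.04, 4))     # BH: max_k (m * p_k / k) = 0.04

  single <- fdr_adjust(res[1, ])
  expect_equal(single$fdr, single$p)

  allone <- res; allone$p <- 1
  expect_equal(fdr_adjust(allone)$fdr, rep(1, 4))

  # insufficient pairs are excluded from the family
  mixed <- res
  mixed$p[2] <- NA; mixed$status[2] <- "insufficient_data"
  adj2 <- fdr_adjust(mixed)
  expect_true(is.na(adj2$fdr[2]))
  expect_equal(adj2$fdr[-2], stats::p.adjust(mixed$p[-2], "BH"))

  # families are per region
  two <- dplyr::bind_rows(res, dplyr::mutate(res, region = "r2", p = p / 10))
  adj3 <- fdr_adjust(two)
  expect_equal(adj3$fdr[adj3$region == "r1"], rep(0.04, 4))
  expect_equal(adj3$fdr[adj3$region == "r2"], rep(0.004, 4))
})

test_that("relabeling the conditions flips every beta exactly", {
  sim <- simulate_tissue(recovery_benchmark_config(), seed = 61)
  fit <- run_differential_proximity(sim$cells, type_level = "cell_type")
  swapped <- sim$cells
  swapped$condition <- factor(
    ifelse(swapped$condition == "reference", "treatment", "reference"),
    levels = c("reference", "treatment"))
  fit2 <- run_differential_proximity(swapped, type_level = "cell_type")
  a <- dplyr::arrange(tidy(fit), region, center_type, surround_type)
  b <- dplyr::arrange(tidy(fit2), region, center_type, surround_type)
  ok <- a$status != "insufficient_data"
  expect_equal(b$beta[ok], -a$beta[ok], tolerance = 1e-6)
  expect_equal(b$p[ok], a$p[ok], tolerance = 1e-5)
})

test_that("scaling all coordinates leaves B-ratios and betas unchanged", {
  sim <- simulate_tissue(null_benchmark_config(), seed = 62)
  cells <- sim$cells
  prox <- compute_proximity(cells, type_level = "cell_type")
  scaled <- cells
  scaled$x <- cells$x * 4.2
  scaled$y <- cells$y * 4.2
  prox2 <- compute_proximity(scaled, type_level = "cell_type")
  expect_equal(prox2$distance_units$d, prox$distance_units$d * 4.2,
               tolerance = 1e-9)
  expect_equal(prox2$observations$b_ratio, prox$observations$b_ratio)
  f1 <- fit_pair(dplyr::filter(prox$observations,
                               center_type == "Astro", surround_type == "Neuron"))
  f2 <- fit_pair(dplyr::filter(prox2$observations,
                               center_type == "Astro", surround_type == "Neuron"))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
})

test_that("the pair matrix is asymmetric with full row/column type sets", {
  sim <- simulate_tissue(recovery_benchmark_config(), seed = 63)
  fit <- run_differential_proximity(sim$cells, type_level = "cell_type")
  bm <- beta_matrix(fit)
  types <- sort(unique(sim$cells$cell_type))
  expect_identical(rownames(bm$beta), types)
  expect_identical(colnames(bm$beta), types)
  expect_false(isTRUE(all.equal(bm$beta, t(bm$beta))))
  expect_identical(dim(bm$significant), dim(bm$beta))

  gl <- glance(fit)
  expect_equal(gl$n_pairs, 9)
  td <- tidy(fit, conf.int = TRUE)
  ok <- td$status != "insufficient_data"
  expect_true(all(td$conf.low[ok] <= td$beta[ok] &
                    td$beta[ok] <= td$conf.high[ok]))
})

test_that("the naive per-cell t test ignores clustering by design", {
  obs <- make_lmm_obs(beta = 0, sample_sd = 0.4, resid_sd = 0.3, seed = 77)
  naive <- fit_pair_naive(obs)
  mixed <- fit_pair(obs)
  expect_true(is.finite(naive$p))
  # the naive test sees thousands of "independent" cells; the mixed model
  # knows there are six samples, so its p-value is far less extreme
  expect_gt(mixed$p, naive$p)
})
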