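test_that("volume filter removes strictly outside [min, 3 x median]", {
  cells <- make_cells(5)
  cells$volume <- c(40, 100, 100, 100, 400)
  res <- filter_by_volume(validate_cell_table(cells))
  expect_equal(sort(res$cells$volume), c(100, 100, 100))
  expect_setequal(res$removed_ids, cells$cell_id[c(1, 5)])

  # boundary cells kept under strict inequalities
  cells$volume <- c(50, 100, 100, 100, 300)   # median 100, 3 x median = 300
  res2 <- filter_by_volume(validate_cell_table(cells))
  expect_equal(nrow(res2$cells), 5)
  expect_length(res2$removed_ids, 0)

  cells$volume <- rep(100, 5)
  expect_equal(nrow(filter_by_volume(validate_cell_table(cells))$cells), 5)

  empty <- validate_cell_table(make_cells(2))[0, ]
  expect_warning(res3 <- filter_by_volume(empty), "empty")
  expect_equal(nrow(res3$cells), 0)
})

test_that("zero-count cells are dropped and missing cells are an error", {
  cells <- validate_cell_table(make_cells(3))
  m <- matrix(c(0, 0, 0, 2, 3, 0, 0, 0, 12), 3, 3, byrow = TRUE,
              dimnames = list(cells$cell_id, c("g1", "g2", "g3")))
  counts <- cellprox:::new_counts_matrix(m)
  res <- drop_zero_count_cells(cells, counts)
  expect_identical(res$removed_ids, cells$cell_id[1])
  expect_equal(nrow(res$cells), 2)

  expect_error(drop_zero_count_cells(cells, counts[2:3, ]),
               cells$cell_id[1])
  allzero <- cellprox:::new_counts_matrix(m * 0)
  expect_warning(res2 <- drop_zero_count_cells(cells, allzero), "zero")
  expect_equal(nrow(res2$cells), 0)
})

test_that("volume normalization is value/volume x 1000 and runs only once", {
  cells <- validate_cell_table(make_cells(3))
  cells$volume <- c(200, 1000, 50)
  m <- matrix(c(10, 0,
                7, 0,
                7, 1), 3, 2, byrow = TRUE,
              dimnames = list(cells$cell_id, c("g1", "g2")))
  counts <- cellprox:::new_counts_matrix(m)
  norm <- normalize_by_volume(counts, cells)
  expect_identical(counts_scale(norm), "volume_normalized")
  expect_equal(unname(norm[1, "g1"]), 50)    # 10 / 200 * 1000
  expect_equal(unname(norm[2, "g1"]), 7)     # volume 1000 is identity
  expect_equal(unname(norm[2, "g2"]), 0)     # zero stays zero
  expect_error(normalize_by_volume(norm, cells), "already")
})

test_that("quantile filter matches an independent type-7 oracle", {
  cells <- validate_cell_table(make_cells(100))
  totals <- 1:100
  m <- matrix(totals, 100, 1, dimnames = list(cells$cell_id, "g1"))
  counts <- cellprox:::new_counts_matrix(m)
  cfg <- qc_config(quantile_scope = "pooled")
  res <- filter_by_total_count_quantiles(cells, counts, cfg)
  lo <- oracle_quantile_type7(totals, 0.02)
  hi <- oracle_quantile_type7(totals, 0.98)
  expect_setequal(res$removed_ids,
                  cells$cell_id[totals < lo | totals > hi])
  expect_gt(length(res$removed_ids), 0)

  # all-identical totals and the full [0, 1] band remove nothing
  m2 <- cellprox:::new_counts_matrix(
    matrix(5, 100, 1, dimnames = list(cells$cell_id, "g1")))
  expect_length(filter_by_total_count_quantiles(cells, m2, cfg)$removed_ids, 0)
  cfg01 <- qc_config(quantile_low = 0, quantile_high = 1,
                     quantile_scope = "pooled")
  expect_length(filter_by_total_count_quantiles(cells, counts, cfg01)$removed_ids, 0)
})

test_that("quantile filtering defaults to per-sample scope", {
  c1 <- make_cells(50, sample_id = "s1", seed = 1)
  c2 <- make_cells(50, sample_id = "s2", seed = 2)
  cells <- validate_cell_table(dplyr::bind_rows(c1, c2))
  # s2 totals are shifted far above s1; pooling would remove all of s1's
  # low tail from the joint distribution, per-sample treats each alone
  totals <- c(1:50, 1001:1050)
  m <- cellprox:::new_counts_matrix(
    matrix(totals, 100, 1, dimnames = list(cells$cell_id, "g1")))
  per <- filter_by_total_count_quantiles(cells, m, qc_config())
  pooled <- filter_by_total_count_quantiles(
    cells, m, qc_config(quantile_scope = "pooled"))
  expect_equal(length(per$removed_ids), 4)     # 2 per sample
  removed_samples <- cells$sample_id[cells$cell_id %in% per$removed_ids]
  expect_setequal(unique(removed_samples), c("s1", "s2"))
  expect_false(setequal(per$removed_ids, pooled$removed_ids))
})

test_that("doublet filter is strict and fails open on missing scores", {
  cells <- make_cells(3)
  cells$doublet_score <- c(0.05, 0.20, 0.21)
  tab <- validate_cell_table(cells)
  res <- filter_doublets(tab)
  expect_setequal(res$cells$doublet_score, c(0.05, 0.20))
  expect_identical(res$removed_ids, cells$cell_id[3])

  cells$doublet_score <- NA_real_
  expect_warning(res2 <- filter_doublets(validate_cell_table(cells)), "no-op")
  expect_equal(nrow(res2$cells), 3)
  expect_equal(res2$n_missing_score, 3)

  cells$doublet_score <- c(0, 0.01, NA)
  res3 <- filter_doublets(validate_cell_table(cells),
                          qc_config(doublet_threshold = 0))
  expect_setequal(res3$cells$cell_id, cells$cell_id[c(1, 3)])
})

test_that("the full cascade reproduces the hand-enumerated fixture", {
  fx <- simulate_qc_fixture(seed = 7)
  qc <- run_qc(fx$cells, fx$counts)
  expect_setequal(qc$cells$cell_id, fx$expected_survivors)
  expect_equal(nrow(qc$cells), 8)
  # telescoping: survivors of stage k are inputs of stage k + 1
  rep <- qc$report
  expect_equal(rep$n_out, rep$n_in - rep$n_removed)
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  expect_equal(rep$n_in[1], 12)
  expect_equal(rep$n_out[nrow(rep)], 8)
  expect_identical(counts_scale(qc$counts), "volume_normalized")
  expect_setequal(rownames(qc$counts), fx$expected_survivors)
})

test_that("stage order matters: the volume median depends on prior removals", {
  # four cells: two mid-volume doublets and one large cell whose fate
  # depends on whether the doublets are still in the median
  cells <- make_cells(4)
  cells$volume <- c(100, 100, 100, 350)
  cells$doublet_score <- c(0.5, 0.5, 0.05, 0.05)
  tab <- validate_cell_table(cells)
  cfg <- qc_config()

  # canonical order: volume first (median 100, bound 300 removes the 350
  # cell), then doublets
  v_first <- filter_doublets(filter_by_volume(tab, cfg)$cells, cfg)
  expect_identical(v_first$cells$cell_id, cells$cell_id[3])

  # reversed order: doublets first shift the median to 225, bound 675,
  # and the large cell survives
  d_first <- filter_by_volume(filter_doublets(tab, cfg)$cells, cfg)
  expect_setequal(d_first$cells$cell_id, cells$cell_id[3:4])
  expect_false(setequal(v_first$cells$cell_id, d_first$cells$cell_id))
})

test_that("a clean table passes the cascade untouched", {
  cells <- make_cells(20)
  cells$doublet_score <- 0.05
  tab <- validate_cell_table(cells)
  m <- cellprox:::new_counts_matrix(
    matrix(10, 20, 2, dimnames = list(tab$cell_id, c("g1", "g2"))))
  qc <- run_qc(tab, m, qc_config(quantile_low = 0, quantile_high = 1))
  expect_equal(nrow(qc$cells), 20)
  expect_true(all(qc$report$n_removed == 0))
})

test_that("stages 1, 2 and 5 are idempotent; widening thresholds is monotone", {
  fx <- simulate_qc_fixture(seed = 3)
  cfg <- qc_config()
  v1 <- filter_by_volume(fx$cells, cfg)
  expect_identical(filter_by_volume(v1$cells, cfg)$cells$cell_id,
                   v1$cells$cell_id)
  z1 <- drop_zero_count_cells(fx$cells, fx$counts)
  expect_identical(drop_zero_count_cells(z1$cells, fx$counts)$cells$cell_id,
                   z1$cells$cell_id)
  d1 <- filter_doublets(fx$cells, cfg)
  expect_identical(filter_doublets(d1$cells, cfg)$cells$cell_id,
                   d1$cells$cell_id)

  for (thr in c(0.1, 0.2, 0.5, 1)) {
    n_lo <- nrow(filter_doublets(fx$cells,
                                 qc_config(doublet_threshold = thr))$cells)
    n_hi <- nrow(filter_doublets(fx$cells,
                                 qc_config(doublet_threshold = thr + 0.2))$cells)
    expect_lte(n_lo, n_hi)
  }
  norm <- normalize_by_volume(fx$counts, fx$cells, cfg)
  for (q in c(0.02, 0.1, 0.25)) {
    wide <- qc_config(quantile_low = q / 2, quantile_high = 1 - q / 2)
    narrow <- qc_config(quantile_low = q, quantile_high = 1 - q)
    expect_lte(
      nrow(filter_by_total_count_quantiles(fx$cells, norm, narrow)$cells),
      nrow(filter_by_total_count_quantiles(fx$cells, norm, wide)$cells))
  }
})
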