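test_that("region_pvalues matches the textbook pooled t-test", {
  set.seed(21)
  labels <- rep(c(1L, 0L), each = 10)
  values <- matrix(rnorm(20 * 6), 20, 6)
  em <- make_entropy_matrix(values, labels)
  pv <- region_pvalues(em)
  for (g in 1:6)
    expect_equal(pv[[g]], ttest_pooled_oracle(values[labels == 1, g],
                                              values[labels == 0, g]))
  # identical class distributions -> p = 1; extreme separation -> tiny p
  same <- make_entropy_matrix(matrix(rep(c(1, 2, 3, 1, 2, 3)), 6, 1),
                              c(1, 1, 1, 0, 0, 0))
  expect_equal(region_pvalues(same)[[1]], 1)
  far <- make_entropy_matrix(
    matrix(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1) + rnorm(10, sd = 1e-4), 10, 1),
    rep(c(1, 0), each = 5))
  expect_lt(region_pvalues(far)[[1]], 1e-6)
})

test_that("masked entries are dropped per region; starved regions give NA", {
  labels <- rep(c(1L, 0L), each = 5)
  values <- matrix(rnorm(10 * 2), 10, 2)
  values[1:4, 2] <- NA  # class 1 left with a single defined value
  pv <- region_pvalues(make_entropy_matrix(values, labels))
  expect_false(is.na(pv[[1]]))
  expect_true(is.na(pv[[2]]))
  expect_equal(significance_count(pv, 1), 1L)  # NA excluded from counts
})

test_that("significance_count applies a strict threshold and ignores NA", {
  expect_equal(significance_count(c(.01, .04, .05, .9), .05), 2L)
  expect_equal(significance_count(c(NA, NA), .05), 0L)
  expect_equal(significance_count(numeric(0), .05), 0L)
})

test_that("select_m returns a grid member with a full count table", {
  ds <- generate_dataset(small_cfg(3))
  grid <- param_grid(r_values = c(0.4, 0.5, 0.6), tau_values = 1:3)
  ms <- select_m(ds, grid)
  expect_true(ms$m_star %in% grid$m_values)
  expect_equal(dim(ms$counts), c(2L, 3L, 3L))
  expect_true(all(ms$counts >= 0 & ms$counts <= 12))
  expect_length(ms$tau_candidates, 2L)
  expect_true(all(ms$tau_candidates %in% grid$tau_values))
})

test_that("select_r and select_tau return grid members and AUC tables in [0, 1]", {
  ds <- generate_dataset(small_cfg(4))
  rs <- select_r(ds, m = 1, tau_candidates = c(2, 3),
                 r_values = seq(0.54, 0.60, 0.02))
  expect_true(rs$r_star %in% seq(0.54, 0.60, 0.02))
  expect_equal(dim(rs$auc_table), c(12L, 4L))
  expect_true(all(rs$auc_table >= 0 & rs$auc_table <= 1, na.rm = TRUE))
  ts <- select_tau(ds, m = 1, r = 0.56, tau_values = 1:5)
  expect_true(ts$tau_star %in% 1:5)
  expect_true(all(ts$auc_table >= 0 & ts$auc_table <= 1, na.rm = TRUE))
  # single-candidate grid is returned unchanged
  expect_equal(select_tau(ds, 1, 0.56, tau_values = 3)$tau_star, 3L)
})

test_that("a fast-dynamics group difference pulls tau toward 1", {
  # group 1 = white noise, group 0 = mildly smoothed AR(0.45): the groups
  # differ at the native resolution and decorrelate by tau = 3
  hits <- sapply(1:6, function(seed) {
    set.seed(seed)
    data <- array(NA_real_, c(12, 6, 200))
    for (s in 1:12) for (g in 1:6) {
      x <- if (s <= 6) rnorm(200) else
        as.numeric(stats::filter(rnorm(210), 0.45, "recursive"))[11:210]
      data[s, g, ] <- (x - mean(x)) / sd(x)
    }
    ds <- make_dataset(data, rep(c(1L, 0L), each = 6))
    select_tau(ds, 1, 0.56, 1:5)$tau_star == 1L
  })
  expect_gte(mean(hits), 0.5)
})

test_that("optimize_all is deterministic, self-consistent and audited", {
  ds <- generate_dataset(small_cfg(5))
  grid <- param_grid(r_values = seq(0.5, 0.6, 0.02),
                     r_refined = seq(0.54, 0.6, 0.02), tau_values = 1:4)
  res1 <- optimize_all(ds, grid)
  res2 <- optimize_all(ds, grid)
  expect_identical(res1$selected, res2$selected)
  expect_identical(res1$m_stage$counts, res2$m_stage$counts)
  expect_true(res1$selected$m %in% grid$m_values)
  expect_true(res1$selected$r %in% grid$r_refined)
  expect_true(res1$selected$tau %in% grid$tau_values)
  expect_length(res1$audit, 3L)
  expect_match(res1$audit[1], "m\\* = ")
  expect_match(res1$audit[3], sprintf("tau\\* = %d", res1$selected$tau))
})

test_that("null data produce near-nominal significance counts for both m", {
  # counts hover around alpha * n_regions on exchangeable groups
  counts <- sapply(1:8, function(seed) {
    ds <- generate_null_dataset(synthetic_config(n_regions = 30,
                                                 planted_regions = integer(0),
                                                 seed = seed))
    em <- entropy_matrix(ds, mse_params(1, 0.56, 2))
    significance_count(region_pvalues(em), 0.05)
  })
  rate <- mean(counts) / 30
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.15)
})
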