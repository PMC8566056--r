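test_that("generator honours shapes, label layout and determinism", {
  cfg <- synthetic_config(seed = 42)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$data), c(20L, 90L, 246L))
  expect_identical(ds$labels, rep(c(1L, 0L), each = 10L))
  expect_identical(generate_dataset(cfg)$data, ds$data)  # bit-identical
  # standardization and no degenerate series
  expect_true(all(abs(apply(ds$data[1:2, 1:5, ], 1:2, mean)) < 1e-12))
  expect_true(all(abs(apply(ds$data[1:2, 1:5, ], 1:2, sd) - 1) < 1e-12))
  expect_false(anyNA(ds$data))
  # a different seed changes the data
  expect_false(identical(generate_dataset(small_cfg(1))$data,
                         generate_dataset(small_cfg(2))$data))
})

test_that("null generator forces the planted set empty; tiny cohorts allowed", {
  cfg <- small_cfg(7)
  ds <- generate_null_dataset(cfg)
  expect_equal(dim(ds$data), c(20L, 12L, 246L))
  expect_identical(ds$provenance$config$planted_regions, integer(0))
  ds2 <- generate_dataset(synthetic_config(n_per_group = 1, n_regions = 3,
                                           planted_regions = integer(0),
                                           seed = 1))
  expect_equal(dim(ds2$data)[1], 2L)
})

test_that("planted_truth reports the configured indices", {
  expect_identical(planted_truth(synthetic_config()),
                   c(17L, 18L, 23L, 29L, 30L, 60L, 67L, 73L, 84L))
  expect_identical(planted_truth(synthetic_config(planted_regions = integer(0))),
                   integer(0))
  expect_identical(planted_truth(synthetic_config(planted_regions = c(5, 1),
                                                  n_regions = 6)),
                   c(1L, 5L))
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(n_per_group = 0), "n_per_group")
  expect_error(synthetic_config(n_timepoints = 20), "n_timepoints")
  expect_error(synthetic_config(planted_regions = c(1, 1)), "planted_regions")
  expect_error(synthetic_config(planted_regions = 91), "planted_regions")
  expect_error(synthetic_config(ar_slow_group1 = 1.2), "ar_slow_group1")
  expect_error(synthetic_config(fast_noise_sd_ratio = -1),
               "fast_noise_sd_ratio")
})

test_that("planted regions separate the groups more than non-planted regions", {
  # mean absolute between-group entropy difference, planted vs not
  p <- mse_params(1, 0.56, 3)
  gaps <- t(sapply(1:6, function(seed) {
    ds <- generate_dataset(small_cfg(seed))
    em <- entropy_matrix(ds, p)$values
    g1 <- ds$labels == 1
    d <- abs(colMeans(em[g1, ]) - colMeans(em[!g1, ]))
    c(planted = mean(d[c(2, 5, 9)]), rest = mean(d[-c(2, 5, 9)]))
  }))
  expect_gt(mean(gaps[, "planted"]), mean(gaps[, "rest"]))
})

test_that("the planted effect is expressed in slow dynamics: larger at tau = 3 than tau = 1", {
  hits <- sapply(1:10, function(seed) {
    ds <- generate_dataset(small_cfg(seed))
    g1 <- ds$labels == 1
    d_at <- function(tau) {
      em <- entropy_matrix(ds, mse_params(1, 0.56, tau))$values
      mean(abs(colMeans(em[g1, c(2, 5, 9)]) - colMeans(em[!g1, c(2, 5, 9)])))
    }
    d_at(3) > d_at(1)
  })
  expect_gte(mean(hits), 0.8)
})
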