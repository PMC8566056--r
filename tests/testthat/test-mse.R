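test_that("coarse-graining averages non-overlapping windows and drops the remainder", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  x <- rnorm(100)
  expect_identical(coarse_grain(x, 1), x)
  expect_length(coarse_grain(rnorm(246), 3), 82L)
  expect_length(coarse_grain(rnorm(247), 3), 82L)  # remainder discarded
  # mean conservation over the truncated window, exactly
  x <- rnorm(47)
  for (tau in c(2, 3, 5)) {
    y <- coarse_grain(x, tau)
    expect_equal(mean(y), mean(x[seq_len(tau * (47 %/% tau))]))
  }
  expect_error(coarse_grain(rnorm(5), 0), "tau")
  expect_error(coarse_grain(rnorm(5), 6), "tau")
})

test_that("sample entropy of a constant series is zero and counts are attached", {
  for (m in 1:2) {
    v <- sample_entropy(rep(3.7, 25), m = m, r_abs = 0.2)
    expect_equal(as.numeric(v), 0)
    cnt <- attr(v, "counts")
    expect_equal(cnt[["A"]], cnt[["B"]])
    expect_gt(cnt[["B"]], 0)
  }
})

test_that("optimized counts equal the literal brute-force enumerator", {
  # the loop enumerator is the definition; also validates the vectorized
  # outer-product oracle used at scale elsewhere
  set.seed(101)
  for (rep in 1:40) {
    L <- sample(8:60, 1)
    y <- rnorm(L)
    m <- sample(1:2, 1)
    r_abs <- runif(1, 0.1, 1.2)
    expected <- sampen_brute(y, m, r_abs)
    expect_identical(unname(attr(sample_entropy(y, m, r_abs), "counts")),
                     unname(as.numeric(expected)))
    expect_identical(unname(sampen_outer(y, m, r_abs)),
                     unname(as.numeric(expected)))
  }
  # worked example: y = 1..8, m = 1, r_abs = 0.5 has no off-diagonal
  # matches at tolerance < 1 except none (gaps are 1), so entropy undefined
  v <- sample_entropy(1:8, 1, 0.5)
  expect_true(is.na(v))
  expect_identical(unname(attr(v, "counts")), c(0, 0))
  # and at r_abs = 1 every adjacent pair matches: counts follow enumeration
  expected <- sampen_brute(1:8, 1, 1.0)
  got <- sample_entropy(1:8, 1, 1.0)
  expect_equal(as.numeric(got), -log(expected[["A"]] / expected[["B"]]))
})

test_that("A <= B always, counts are non-decreasing in r, entropy non-negative", {
  set.seed(202)
  for (rep in 1:20) {
    y <- rnorm(sample(30:120, 1))
    m <- sample(1:2, 1)
    rs <- seq(0.1, 1.5, by = 0.1)
    cnt <- mselat:::.sampen_counts(y, m, rs)
    expect_true(all(cnt[2, ] <= cnt[1, ]))         # every (m+1)-match is an m-match
    expect_true(all(diff(cnt[1, ]) >= 0))          # counts non-decreasing in r
    expect_true(all(diff(cnt[2, ]) >= 0))
    ent <- ifelse(cnt[2, ] > 0, -log(cnt[2, ] / cnt[1, ]), NA)
    expect_true(all(ent >= 0, na.rm = TRUE))
  }
  # entropy decreases with r as a large-sample tendency (the match-count
  # RATIO is not pointwise monotone on short series, unlike the counts)
  for (rep in 1:5) {
    y <- rnorm(2000)
    cnt <- mselat:::.sampen_counts(y, 1, seq(0.3, 0.6, 0.02))
    ent <- -log(cnt[2, ] / cnt[1, ])
    expect_lt(ent[length(ent)], ent[1])
  }
})

test_that("mse_value composes sd scaling, coarse-graining and sample entropy", {
  set.seed(303)
  x <- rnorm(246, sd = 2.5)
  p <- mse_params(1, 0.56, 3)
  manual <- sampen_outer(coarse_grain(x, 3), 1, 0.56 * sd(x))
  expect_equal(mse_value(x, p), -log(manual[["A"]] / manual[["B"]]))
  # constant series: zero for any parameters
  expect_equal(mse_value(rep(2, 100), p), 0)
  # tau = 1 on a standardized series reduces to plain sample entropy
  z <- (x - mean(x)) / sd(x)
  expect_equal(mse_value(z, mse_params(1, 0.56, 1)),
               as.numeric(sample_entropy(z, 1, 0.56 * sd(z))))
})

test_that("entropy_matrix equals an element-wise loop over mse_value", {
  ds <- generate_dataset(synthetic_config(n_per_group = 3, n_regions = 4,
                                          n_timepoints = 60,
                                          planted_regions = 1L, seed = 5))
  p <- mse_params(2, 0.4, 2)
  em <- entropy_matrix(ds, p)
  expect_equal(dim(em$values), c(6L, 4L))
  for (s in 1:6)
    for (g in 1:4)
      expect_equal(em$values[s, g], mse_value(ds$data[s, g, ], p))
  expect_identical(em$undefined, is.na(em$values))
})

test_that("white-noise entropy decays with scale (fewer samples, averaging)", {
  set.seed(404)
  e1 <- e3 <- numeric(50)
  for (k in 1:50) {
    x <- rnorm(246)
    e1[k] <- mse_value(x, mse_params(1, 0.56, 1))
    e3[k] <- mse_value(x, mse_params(1, 0.56, 3))
  }
  expect_lt(mean(e3), mean(e1))
})

test_that("undefined entropies are masked, not thrown", {
  # tiny tolerance on a short irregular series: no matches
  y <- c(0, 10, -7, 23, 5, -14, 31, 2, -9, 18)
  v <- sample_entropy(y, 1, 1e-6)
  expect_true(is.na(as.numeric(v)))
  data <- array(0, c(1, 2, 10))
  data[1, 1, ] <- y
  data[1, 2, ] <- y + 1
  ds <- make_dataset(data, labels = 1L)
  em <- entropy_matrix(ds, mse_params(1, 1e-9, 1))
  expect_true(all(em$undefined))
})
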