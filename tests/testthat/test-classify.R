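test_that("build_features subsets columns in biomarker order and imputes masks", {
  labels <- rep(c(1L, 0L), each = 5)
  values <- matrix(rnorm(10 * 6), 10, 6,
                   dimnames = list(NULL, sprintf("R%02d", 1:6)))
  em <- make_entropy_matrix(values, labels)
  bs <- select_biomarkers(em, alpha_final = 1.0)  # all regions
  f <- build_features(em, bs)
  expect_equal(unname(f), unname(values))
  # subset keeps biomarker order
  bs2 <- bs
  bs2$region_indices <- c(5L, 2L)
  bs2$region_names <- em$region_names[c(5, 2)]
  f2 <- build_features(em, bs2)
  expect_equal(unname(f2), unname(values[, c(5, 2)]))
  expect_identical(colnames(f2), c("R05", "R02"))
  # masked entry imputed by the column mean of the defined entries
  em$values[1, 2] <- NA
  expect_message(f3 <- build_features(em, bs), "imputed")
  expect_equal(f3[1, 2], mean(values[-1, 2]))
  # empty set is an instructive error
  bs_empty <- bs
  bs_empty$region_indices <- integer(0)
  expect_error(build_features(em, bs_empty), "alpha")
})

test_that("grid search finds a separating (C, g) on separable clusters", {
  set.seed(41)
  f <- rbind(matrix(rnorm(10 * 2), 10, 2), matrix(rnorm(10 * 2, 6), 10, 2))
  labels <- rep(c(1L, 0L), each = 10)
  res <- grid_search_svm(f, labels, fast_svm_cfg())
  expect_equal(res$cv_score, 1.0)
  expect_true(res$C_star %in% 2^seq(-10, 10, 2.5))
  # a single-point grid returns that point
  one <- svm_grid_config(exponent_range = c(0, 0.1), exponent_step = 1,
                         inner_cv_folds = 2)
  res1 <- grid_search_svm(f, labels, one)
  expect_equal(res1$C_star, 1); expect_equal(res1$g_star, 1)
})

test_that("loocv bookkeeping: one row per subject, accuracy = #T / N, deterministic", {
  labels <- c(1L, 1L, 1L, 0L, 0L, 0L)
  values <- cbind(c(5.1, 4.9, 5.3, 0.2, -0.1, 0.4),
                  c(3.0, 3.2, 2.8, -2.9, -3.1, -3.0))
  colnames(values) <- c("R01", "R02")
  em <- make_entropy_matrix(values, labels)
  bs <- select_biomarkers(em, alpha_final = 1.0)
  toy_cfg <- svm_grid_config(exponent_step = 2.5, inner_cv_folds = 2)
  cv <- loocv(em, bs, cfg = toy_cfg)
  expect_equal(nrow(cv$per_subject), 6L)
  expect_identical(cv$per_subject$true_label, labels)
  expect_equal(cv$mean_accuracy, sum(cv$per_subject$correct) / 6)
  expect_equal(cv$mean_accuracy, 1.0)  # trivially separated toy
  cv2 <- loocv(em, bs, cfg = toy_cfg)
  expect_identical(cv$per_subject, cv2$per_subject)
})

test_that("loocv on a strong-effect planted dataset is highly accurate", {
  cfg <- small_cfg(9)
  ds <- generate_dataset(cfg)
  em <- entropy_matrix(ds, mse_params(1, 0.56, 5))
  bs <- select_biomarkers(em, alpha_final = 0.05)
  cv <- loocv(em, bs, cfg = fast_svm_cfg())
  expect_gte(cv$mean_accuracy, 0.8)
})

test_that("nested selection re-selects features inside each fold", {
  cfg <- small_cfg(10)
  ds <- generate_dataset(cfg)
  em <- entropy_matrix(ds, mse_params(1, 0.56, 5))
  bs <- select_biomarkers(em, alpha_final = 0.05)
  cv <- loocv(em, bs, cfg = fast_svm_cfg(selection_scope = "nested"))
  expect_equal(nrow(cv$per_subject), 20L)
  expect_true(all(cv$per_subject$predicted_label %in% 0:1))
})

test_that("holdout split is class-balanced; separable features score 1.0", {
  labels <- rep(c(1L, 0L), each = 10)
  values <- cbind(c(rnorm(10, 5), rnorm(10, -5)),
                  c(rnorm(10, 4), rnorm(10, -4)))
  colnames(values) <- c("R01", "R02")
  em <- make_entropy_matrix(values, labels)
  bs <- select_biomarkers(em, alpha_final = 1.0)
  res <- holdout_eval(em, bs, train_n = 8, seed = 3, cfg = fast_svm_cfg())
  expect_length(res$train_idx, 8L)
  expect_length(res$test_idx, 12L)
  expect_equal(sum(labels[res$train_idx]), 4L)  # 4 + 4 balanced
  expect_equal(res$accuracy, 1.0)
  # same seed reproduces the split, different seed moves it
  res2 <- holdout_eval(em, bs, train_n = 8, seed = 3, cfg = fast_svm_cfg())
  expect_identical(res$train_idx, res2$train_idx)
  expect_error(holdout_eval(em, bs, train_n = 20), "smaller")
})
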