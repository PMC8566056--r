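# Independent oracles and small fixture builders used across the suite.

# Literal O(L^2 * m) sample-entropy pair enumerator: ordered pairs i != j,
# templates of length m and m+1 over start positions 1..L-m, Chebyshev
# distance <= r_abs. Written loop-for-loop from the estimator's definition.
sampen_brute <- function(y, m, r_abs) {
  L <- length(y)
  n <- L - m
  A <- B <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dm <- max(abs(y[i:(i + m - 1L)] - y[j:(j + m - 1L)]))
      if (dm <= r_abs) B <- B + 2L
      dmp <- max(dm, abs(y[i + m] - y[j + m]))
      if (dmp <= r_abs) A <- A + 2L
    }
  }
  c(A = A, B = B)
}

# Matrix-algebra enumerator of the same counts (outer-product distances);
# an independent vectorized path fast enough for thousands of series.
sampen_outer <- function(y, m, r_abs) {
  L <- length(y)
  n <- L - m
  idx <- seq_len(n)
  dm <- matrix(0, n, n)
  for (k in 0:(m - 1L))
    dm <- pmax(dm, abs(outer(y[idx + k], y[idx + k], "-")))
  dmp <- pmax(dm, abs(outer(y[idx + m], y[idx + m], "-")))
  # subtract the n diagonal self-matches (distance 0 <= r_abs)
  c(A = as.numeric(sum(dmp <= r_abs) - n), B = as.numeric(sum(dm <= r_abs) - n))
}

# Exhaustive Mann-Whitney pair counting.
auc_brute <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

trapezoid_area <- function(curve) {
  x <- curve$fpr; y <- curve$tpr
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Pooled-variance two-sample t-test from the textbook formula.
ttest_pooled_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), df = n1 + n2 - 2)
}

# Wrap a plain array as a roi_dataset for hand-constructed fixtures.
make_dataset <- function(data, labels,
                         region_names = sprintf("R%02d", seq_len(dim(data)[2]))) {
  subject_ids <- sprintf("sub-%02d", seq_len(dim(data)[1]))
  dimnames(data) <- list(subject_ids, region_names, NULL)
  structure(list(data = data, labels = as.integer(labels),
                 subject_ids = subject_ids, region_names = region_names,
                 provenance = list(generator = "test fixture")),
            class = "roi_dataset")
}

# Wrap a values matrix as an entropy_matrix.
make_entropy_matrix <- function(values, labels, params = mse_params()) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sub-%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("R%02d", seq_len(ncol(values)))
  structure(list(values = values, undefined = is.na(values), params = params,
                 labels = as.integer(labels),
                 region_names = colnames(values)),
            class = "entropy_matrix")
}

# Coarse SVM search grid keeping cross-validation loops affordable in
# repeated Monte-Carlo tests; resolution does not affect what those tests
# measure (separability or chance level).
fast_svm_cfg <- function(...) {
  svm_grid_config(exponent_range = c(-10, 10), exponent_step = 2.5,
                  inner_cv_folds = 3L, ...)
}

# Small planted configuration for quick module-level checks.
small_cfg <- function(seed, ...) {
  synthetic_config(n_regions = 12L, planted_regions = c(2L, 5L, 9L),
                   seed = seed, ...)
}
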