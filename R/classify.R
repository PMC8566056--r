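#' RBF-SVM grid-search configuration
#'
#' Both the cost `C` and the kernel parameter `g = 1/(2 * sigma^2)` are
#' searched on a base-2 exponent grid: raw values `base^a` for `a` from
#' `exponent_range[1]` to `exponent_range[2]` in steps of `exponent_step`
#' (defaults: exponents -10..10, step 0.2 — 101 values each). Exponents of
#' 2 are the standard libsvm reading of such a range (a raw negative cost
#' would be meaningless).
#'
#' @param exponent_range Length-2 numeric, lo < hi (default c(-10, 10)).
#' @param exponent_step Positive step on the exponent scale (default 0.2).
#' @param base Base of the exponentiation (default 2).
#' @param inner_cv_folds Stratified folds for the inner model-selection CV
#'   (default 5; reduced with a warning when a class is smaller).
#' @param standardize Standardize features with training-fold mean/sd
#'   before fitting (default TRUE; RBF kernels are scale-sensitive).
#' @param selection_scope `"fixed_biomarkers"` (biomarkers chosen once on
#'   the full data, the replicated procedure) or `"nested"` (re-selected
#'   inside every cross-validation fold; leakage-free).
#' @return An `svm_grid_config` object.
#' @export
svm_grid_config <- function(exponent_range = c(-10, 10),
                            exponent_step = 0.2,
                            base = 2,
                            inner_cv_folds = 5L,
                            standardize = TRUE,
                            selection_scope = c("fixed_biomarkers", "nested")) {
  stopifnot(length(exponent_range) == 2L,
            exponent_range[1L] < exponent_range[2L],
            exponent_step > 0, base > 0, inner_cv_folds >= 2L)
  structure(list(exponent_range = as.numeric(exponent_range),
                 exponent_step = exponent_step, base = base,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 standardize = isTRUE(standardize),
                 selection_scope = match.arg(selection_scope)),
            class = "svm_grid_config")
}

.exponent_grid <- function(cfg) {
  e <- seq(cfg$exponent_range[1L], cfg$exponent_range[2L],
           by = cfg$exponent_step)
  cfg$base ^ e
}

#' Feature table from an entropy matrix and a biomarker set
#'
#' Column subset of the entropy matrix over the biomarker regions, in
#' biomarker order. Masked (undefined) entries are imputed with the
#' region's column mean over defined entries.
#'
#' @param mat An [entropy_matrix()] at the biomarker set's parameters.
#' @param bs A non-empty `biomarker_set`.
#' @return Numeric matrix, subjects x biomarkers.
#' @export
build_features <- function(mat, bs) {
  stopifnot(inherits(mat, "entropy_matrix"), inherits(bs, "biomarker_set"))
  if (length(bs$region_indices) == 0L)
    stop("empty biomarker set: no features to build; relax alpha_final",
         call. = FALSE)
  f <- mat$values[, bs$region_indices, drop = FALSE]
  colnames(f) <- bs$region_names
  for (j in seq_len(ncol(f))) {
    miss <- is.na(f[, j])
    if (any(miss)) {
      f[miss, j] <- mean(f[!miss, j])
      message(sprintf("build_features: imputed %d undefined value(s) in %s",
                      sum(miss), colnames(f)[j]))
    }
  }
  f
}

# stratified fold assignment (deterministic: round-robin within class by
# subject order)
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Exhaustive search over the (C, g) grid of `cfg`, scoring each pair by
#' stratified k-fold cross-validated accuracy on the given data. Ties
#' break toward the smallest C, then the smallest g. Features are
#' standardized with training-fold statistics when `cfg$standardize`.
#'
#' @param features Numeric matrix, subjects x features.
#' @param labels Binary labels (0/1), both classes present.
#' @param cfg An [svm_grid_config()].
#' @return List with `C_star`, `g_star`, `cv_score`.
#' @export
grid_search_svm <- function(features, labels, cfg = svm_grid_config()) {
  stopifnot(inherits(cfg, "svm_grid_config"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0L, 1L)))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present", call. = FALSE)
  k <- min(cfg$inner_cv_folds, sum(labels == 1L), sum(labels == 0L))
  if (k < cfg$inner_cv_folds)
    warning(sprintf("inner CV folds reduced to %d (smallest class size)", k))
  vals <- .exponent_grid(cfg)
  yf <- factor(labels, levels = c(0L, 1L))
  # k == 1 (a singleton class) degenerates to resubstitution scoring
  fold <- if (k >= 2L) .stratified_folds(labels, k) else rep(0L, length(labels))

  # precompute per-fold standardized train/test splits once
  splits <- lapply(seq_len(max(k, 1L)), function(f) {
    tr <- if (k >= 2L) fold != f else rep(TRUE, length(labels))
    te <- if (k >= 2L) !tr else tr
    xtr <- features[tr, , drop = FALSE]
    xte <- features[te, , drop = FALSE]
    if (cfg$standardize) {
      mu <- colMeans(xtr)
      s <- apply(xtr, 2L, stats::sd)
      s[s == 0 | is.na(s)] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, s, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, s, "/")
    }
    list(xtr = xtr, ytr = yf[tr], xte = xte, yte = yf[te])
  })

  best <- list(score = -1, C = NA_real_, g = NA_real_)
  for (C in vals) {
    for (g in vals) {
      correct <- 0L
      for (sp in splits) {
        fit <- e1071::svm(sp$xtr, sp$ytr, type = "C-classification",
                          kernel = "radial", cost = C, gamma = g,
                          scale = FALSE)
        correct <- correct + sum(predict(fit, sp$xte) == sp$yte)
      }
      score <- correct / length(labels)
      if (score > best$score) best <- list(score = score, C = C, g = g)
    }
  }
  list(C_star = best$C, g_star = best$g, cv_score = best$score)
}

#' Leave-one-out cross-validated hemisphere classification
#'
#' For each held-out subject, runs the (C, g) grid search on the remaining
#' subjects, fits the RBF SVM at the winning pair, and predicts the
#' held-out label. With `cfg$selection_scope = "fixed_biomarkers"` the
#' feature set (biomarker regions) is fixed from the full data — the
#' replicated small-sample procedure, optimistically biased on null data.
#' With `"nested"` the biomarkers are re-selected from the training
#' subjects of every fold (falling back to the single best-p region when
#' none passes `alpha_final`), which is leakage-free and calibrated at
#' chance on null data.
#'
#' @param mat An [entropy_matrix()] at the optimized parameters.
#' @param bs A `biomarker_set` (used directly under `fixed_biomarkers`;
#'   its `alpha_final` is reused for per-fold selection under `nested`).
#' @param labels Binary subject labels (taken from `mat` when omitted).
#' @param cfg An [svm_grid_config()].
#' @return A `loocv_result`: list with `per_subject` (data.frame:
#'   subject, true_label, predicted_label, correct, C_used, g_used),
#'   `mean_accuracy`, and `config`.
#' @export
loocv <- function(mat, bs, labels = NULL, cfg = svm_grid_config()) {
  stopifnot(inherits(mat, "entropy_matrix"), inherits(bs, "biomarker_set"),
            inherits(cfg, "svm_grid_config"))
  if (is.null(labels)) labels <- mat$labels
  labels <- as.integer(labels)
  n <- nrow(mat$values)
  stopifnot(n >= 3L, length(labels) == n)
  nested <- cfg$selection_scope == "nested"
  feats_full <- if (!nested) build_features(mat, bs) else NULL

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (nested) {
      sub <- mat
      sub$values <- mat$values[tr, , drop = FALSE]
      sub$undefined <- mat$undefined[tr, , drop = FALSE]
      sub$labels <- labels[tr]
      bs_i <- select_biomarkers(sub, alpha_final = bs$alpha_final)
      if (length(bs_i$region_indices) == 0L) {
        # fall back to the most discriminative region so a prediction exists
        best <- which.min(bs_i$all_pvalues)
        bs_i$region_indices <- best
        bs_i$region_names <- mat$region_names[best]
      }
      f_tr <- mat$values[tr, bs_i$region_indices, drop = FALSE]
      f_te <- mat$values[i, bs_i$region_indices, drop = FALSE]
      for (j in seq_len(ncol(f_tr))) {  # impute from training fold only
        miss <- is.na(f_tr[, j])
        if (any(miss)) f_tr[miss, j] <- mean(f_tr[!miss, j])
        if (is.na(f_te[1L, j])) f_te[1L, j] <- mean(f_tr[, j])
      }
    } else {
      f_tr <- feats_full[tr, , drop = FALSE]
      f_te <- feats_full[i, , drop = FALSE]
    }
    gs <- grid_search_svm(f_tr, labels[tr], cfg)
    xtr <- f_tr; xte <- f_te
    if (cfg$standardize) {
      mu <- colMeans(xtr)
      s <- apply(xtr, 2L, stats::sd)
      s[s == 0 | is.na(s)] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, s, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, s, "/")
    }
    fit <- e1071::svm(xtr, factor(labels[tr], levels = c(0L, 1L)),
                      type = "C-classification", kernel = "radial",
                      cost = gs$C_star, gamma = gs$g_star, scale = FALSE)
    pred <- as.integer(as.character(predict(fit, xte)))
    rows[[i]] <- data.frame(subject = rownames(mat$values)[i],
                            true_label = labels[i], predicted_label = pred,
                            correct = pred == labels[i],
                            C_used = gs$C_star, g_used = gs$g_star)
  }
  per_subject <- do.call(rbind, rows)
  structure(list(per_subject = per_subject,
                 mean_accuracy = sum(per_subject$correct) / n,
                 config = cfg),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  n <- nrow(x$per_subject)
  cat(sprintf("LOOCV: %d/%d correct, mean accuracy %.3f\n",
              sum(x$per_subject$correct), n, x$mean_accuracy))
  cat(" ", paste(ifelse(x$per_subject$correct, "T", "F"), collapse = " "),
      "\n")
  invisible(x)
}

#' Single class-balanced holdout evaluation
#'
#' Random class-balanced split into `train_n` training subjects and the
#' rest for testing (the small-cohort variant uses 8 training and 12 test
#' subjects); (C, g) grid search on the training set, accuracy on the
#' test set.
#'
#' @param mat An [entropy_matrix()].
#' @param bs A non-empty `biomarker_set`.
#' @param labels Binary subject labels (taken from `mat` when omitted).
#' @param train_n Training-set size (default 8); split as evenly as the
#'   class sizes allow.
#' @param seed RNG seed for the split.
#' @param cfg An [svm_grid_config()].
#' @return List with `accuracy`, `train_idx`, `test_idx`, `C_star`,
#'   `g_star`.
#' @export
holdout_eval <- function(mat, bs, labels = NULL, train_n = 8L, seed = 1L,
                         cfg = svm_grid_config()) {
  stopifnot(inherits(mat, "entropy_matrix"))
  if (is.null(labels)) labels <- mat$labels
  labels <- as.integer(labels)
  n <- length(labels)
  train_n <- as.integer(train_n)
  if (train_n >= n) stop("train_n must be smaller than the subject count",
                         call. = FALSE)
  n1 <- train_n %/% 2L; n0 <- train_n - n1
  if (n1 < 1L || n0 < 1L || n1 > sum(labels == 1L) || n0 > sum(labels == 0L))
    stop("cannot form a class-balanced training split of size ", train_n,
         call. = FALSE)
  set.seed(as.integer(seed))
  tr <- c(sample(which(labels == 1L), n1), sample(which(labels == 0L), n0))
  te <- setdiff(seq_len(n), tr)
  feats <- build_features(mat, bs)
  gs <- grid_search_svm(feats[tr, , drop = FALSE], labels[tr], cfg)
  xtr <- feats[tr, , drop = FALSE]; xte <- feats[te, , drop = FALSE]
  if (cfg$standardize) {
    mu <- colMeans(xtr); s <- apply(xtr, 2L, stats::sd)
    s[s == 0 | is.na(s)] <- 1
    xtr <- sweep(sweep(xtr, 2L, mu), 2L, s, "/")
    xte <- sweep(sweep(xte, 2L, mu), 2L, s, "/")
  }
  fit <- e1071::svm(xtr, factor(labels[tr], levels = c(0L, 1L)),
                    type = "C-classification", kernel = "radial",
                    cost = gs$C_star, gamma = gs$g_star, scale = FALSE)
  pred <- as.integer(as.character(predict(fit, xte)))
  list(accuracy = mean(pred == labels[te]), train_idx = tr, test_idx = te,
       C_star = gs$C_star, g_star = gs$g_star)
}
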