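#' Parameter search grid
#'
#' The (m, r, tau) grid and screening settings for the three-stage entropy
#' parameter optimization: `m` by intergroup significance counts over the
#' whole (tau, r) grid, then `r` by per-region AUC over a refined r range
#' at the best-counting scales, then `tau` by per-region AUC at the chosen
#' (m, r).
#'
#' @param m_values Candidate embedding dimensions (default 1:2).
#' @param r_values Similarity factors for the counting stage (default 0.30
#'   to 0.60, step 0.02).
#' @param r_refined Similarity factors for the AUC-based r stage (default
#'   0.54 to 0.60, step 0.02).
#' @param tau_values Candidate scale factors (default 1:5).
#' @param alpha_screen Screening significance level for the counting stage
#'   (default 0.05).
#' @param top_k Number of top regions whose folded AUCs are averaged when
#'   scoring an r or tau setting (default 2).
#' @param n_tau_candidates How many of the best-counting scales feed the r
#'   stage (default 2).
#' @param welch Use Welch's t-test instead of the pooled-variance Student
#'   test (default FALSE).
#' @return A `param_grid` object.
#' @export
param_grid <- function(m_values = c(1L, 2L),
                       r_values = seq(0.30, 0.60, by = 0.02),
                       r_refined = seq(0.54, 0.60, by = 0.02),
                       tau_values = 1:5,
                       alpha_screen = 0.05,
                       top_k = 2L,
                       n_tau_candidates = 2L,
                       welch = FALSE) {
  stopifnot(length(m_values) >= 1L, length(r_values) >= 1L,
            length(r_refined) >= 1L, length(tau_values) >= 1L,
            alpha_screen > 0, alpha_screen < 1, top_k >= 1L,
            n_tau_candidates >= 1L)
  structure(list(m_values = sort(as.integer(m_values)),
                 r_values = sort(r_values), r_refined = sort(r_refined),
                 tau_values = sort(as.integer(tau_values)),
                 alpha_screen = alpha_screen, top_k = as.integer(top_k),
                 n_tau_candidates = as.integer(n_tau_candidates),
                 welch = isTRUE(welch)),
            class = "param_grid")
}

#' Per-region two-sample t-test p-values
#'
#' Two-sided two-sample t-test (pooled-variance Student by default, Welch
#' optionally) comparing the two label groups region by region. Undefined
#' entropy entries are dropped per region; a region left with fewer than
#' two defined values in either class gets `NA`.
#'
#' @param mat An [entropy_matrix()], or a plain subjects x regions matrix.
#' @param labels Binary subject labels (taken from `mat` when omitted).
#' @param welch Use Welch's unequal-variance test (default FALSE).
#' @return Numeric vector of p-values, one per region (`NA` where the test
#'   is undefined).
#' @export
region_pvalues <- function(mat, labels = NULL, welch = FALSE) {
  v <- if (inherits(mat, "entropy_matrix")) mat$values else as.matrix(mat)
  if (is.null(labels) && inherits(mat, "entropy_matrix")) labels <- mat$labels
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(v), all(labels %in% c(0L, 1L)))
  apply(v, 2L, function(col) {
    a <- col[labels == 1L & !is.na(col)]
    b <- col[labels == 0L & !is.na(col)]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b, var.equal = !welch)$p.value
  })
}

#' Count significant regions
#'
#' Number of defined p-values strictly below `alpha`.
#'
#' @param pvals Numeric p-values (may contain `NA`).
#' @param alpha Significance level.
#' @return Integer count.
#' @export
significance_count <- function(pvals, alpha = 0.05) {
  sum(pvals < alpha, na.rm = TRUE)
}

# fold an AUC for ranking: a region consistently lower in the positive
# group is as sensitive as one consistently higher
.fold <- function(a) pmax(a, 1 - a)

# per-region AUC of an entropy value matrix
.region_aucs <- function(values, labels) {
  apply(values, 2L, function(col) {
    keep <- !is.na(col)
    if (!any(labels[keep] == 1L) || !any(labels[keep] == 0L)) return(NA_real_)
    auc(col[keep], labels[keep])
  })
}

# mean of the top_k folded AUCs (ranking score for one grid setting)
.topk_score <- function(aucs, top_k) {
  f <- .fold(aucs[!is.na(aucs)])
  if (length(f) == 0L) return(NA_real_)
  mean(sort(f, decreasing = TRUE)[seq_len(min(top_k, length(f)))])
}

#' Select the embedding dimension m by significance counts
#'
#' For every (m, tau, r) cell of the grid, computes the entropy matrix and
#' counts regions whose intergroup t-test gives p below `alpha_screen`.
#' The selected `m` maximizes the grand mean count across the (tau, r)
#' grid; ties break toward the smaller m.
#'
#' @param ds A `roi_dataset`.
#' @param grid A [param_grid()].
#' @return List with `m_star`, `counts` (3-d array m x tau x r),
#'   `mean_counts` (per m), and `tau_candidates` (the `n_tau_candidates`
#'   scales with the highest mean count at `m_star`, ascending).
#' @export
select_m <- function(ds, grid = param_grid()) {
  stopifnot(inherits(ds, "roi_dataset"), inherits(grid, "param_grid"))
  eg <- entropy_grid(ds, grid$m_values, grid$r_values, grid$tau_values)
  counts <- array(0L, dim = dim(eg)[1:3], dimnames = dimnames(eg)[1:3])
  for (mi in seq_along(grid$m_values))
    for (ti in seq_along(grid$tau_values))
      for (ri in seq_along(grid$r_values)) {
        pv <- region_pvalues(eg[mi, ti, ri, , ], ds$labels, welch = grid$welch)
        counts[mi, ti, ri] <- significance_count(pv, grid$alpha_screen)
      }
  mean_counts <- apply(counts, 1L, mean)
  m_star <- grid$m_values[which.max(mean_counts)]  # ties -> smaller m
  tau_means <- apply(counts[which.max(mean_counts), , , drop = FALSE],
                     2L, mean)
  ord <- order(-tau_means, grid$tau_values)  # highest count, tie -> smaller tau
  tau_candidates <- sort(grid$tau_values[ord[seq_len(
    min(grid$n_tau_candidates, length(grid$tau_values)))]])
  list(m_star = m_star, counts = counts, mean_counts = mean_counts,
       tau_candidates = tau_candidates)
}

#' Select the similarity factor r by per-region AUC
#'
#' At fixed `m`, for each candidate scale and each r in `r_values`,
#' computes per-region AUCs of the entropy values; the score of an r is
#' the mean over candidate scales of the mean of the `top_k` largest
#' *folded* AUCs (`max(AUC, 1 - AUC)`). The selected r maximizes the
#' score; ties break toward the smaller r. Reported AUC tables are
#' unfolded.
#'
#' @param ds A `roi_dataset`.
#' @param m Embedding dimension.
#' @param tau_candidates Scales to average over.
#' @param r_values Candidate similarity factors.
#' @param top_k Regions entering the score.
#' @return List with `r_star`, `scores` (per r), and `auc_table`
#'   (regions x r, averaged over candidate scales, unfolded).
#' @export
select_r <- function(ds, m, tau_candidates, r_values, top_k = 2L) {
  stopifnot(inherits(ds, "roi_dataset"))
  r_values <- sort(r_values)
  eg <- entropy_grid(ds, m, r_values, tau_candidates)
  ng <- dim(ds$data)[2L]
  scores <- numeric(length(r_values))
  auc_sum <- matrix(0, ng, length(r_values),
                    dimnames = list(ds$region_names, sprintf("r%.2f", r_values)))
  for (ri in seq_along(r_values)) {
    per_tau <- sapply(seq_along(tau_candidates), function(ti) {
      a <- .region_aucs(eg[1L, ti, ri, , ], ds$labels)
      auc_sum[, ri] <<- auc_sum[, ri] + ifelse(is.na(a), 0, a)
      .topk_score(a, top_k)
    })
    scores[ri] <- mean(per_tau, na.rm = TRUE)
  }
  list(r_star = r_values[which.max(scores)], scores = scores,
       auc_table = auc_sum / length(tau_candidates))
}

#' Select the scale factor tau by per-region AUC
#'
#' Same scoring as [select_r()] with the roles of r and tau swapped: at
#' fixed (m, r), each scale is scored by the mean of its `top_k` folded
#' per-region AUCs; ties break toward the smaller tau.
#'
#' @param ds A `roi_dataset`.
#' @param m Embedding dimension.
#' @param r Similarity factor.
#' @param tau_values Candidate scales.
#' @param top_k Regions entering the score.
#' @return List with `tau_star`, `scores` (per tau), and `auc_table`
#'   (regions x tau, unfolded).
#' @export
select_tau <- function(ds, m, r, tau_values, top_k = 2L) {
  stopifnot(inherits(ds, "roi_dataset"))
  tau_values <- sort(as.integer(tau_values))
  eg <- entropy_grid(ds, m, r, tau_values)
  ng <- dim(ds$data)[2L]
  auc_table <- matrix(NA_real_, ng, length(tau_values),
                      dimnames = list(ds$region_names,
                                      paste0("tau", tau_values)))
  scores <- numeric(length(tau_values))
  for (ti in seq_along(tau_values)) {
    a <- .region_aucs(eg[1L, ti, 1L, , ], ds$labels)
    auc_table[, ti] <- a
    scores[ti] <- .topk_score(a, top_k)
  }
  list(tau_star = tau_values[which.max(scores)], scores = scores,
       auc_table = auc_table)
}

#' Full three-stage (m, r, tau) optimization
#'
#' Runs [select_m()] (significance counts over the whole grid), then
#' [select_r()] over the refined r range at the best-counting scales, then
#' [select_tau()] at the chosen (m, r). Deterministic given the dataset.
#'
#' @param ds A `roi_dataset`.
#' @param grid A [param_grid()].
#' @return A `param_search_result`: list with `selected` ([mse_params()]),
#'   `m_stage`, `r_stage`, `tau_stage`, and `audit` (per-stage rationale
#'   strings).
#' @export
optimize_all <- function(ds, grid = param_grid()) {
  stopifnot(inherits(ds, "roi_dataset"), inherits(grid, "param_grid"))
  ms <- select_m(ds, grid)
  audit <- sprintf(
    "m stage: mean significant-region counts per m = [%s]; m* = %d; tau candidates by count = [%s]",
    paste(sprintf("%.2f", ms$mean_counts), collapse = ", "), ms$m_star,
    paste(ms$tau_candidates, collapse = ", "))
  rs <- select_r(ds, ms$m_star, ms$tau_candidates, grid$r_refined, grid$top_k)
  audit <- c(audit, sprintf(
    "r stage: top-%d folded-AUC scores over r = [%s] -> [%s]; r* = %.2f",
    grid$top_k, paste(sprintf("%.2f", sort(grid$r_refined)), collapse = ", "),
    paste(sprintf("%.3f", rs$scores), collapse = ", "), rs$r_star))
  ts <- select_tau(ds, ms$m_star, rs$r_star, grid$tau_values, grid$top_k)
  audit <- c(audit, sprintf(
    "tau stage: top-%d folded-AUC scores over tau = [%s] -> [%s]; tau* = %d",
    grid$top_k, paste(grid$tau_values, collapse = ", "),
    paste(sprintf("%.3f", ts$scores), collapse = ", "), ts$tau_star))
  structure(list(selected = mse_params(ms$m_star, rs$r_star, ts$tau_star),
                 m_stage = ms, r_stage = rs, tau_stage = ts, audit = audit),
            class = "param_search_result")
}

#' @export
print.param_search_result <- function(x, ...) {
  cat("Entropy parameter search\n")
  for (line in x$audit) cat(" ", line, "\n")
  cat(sprintf("Selected: m = %d, r = %g, tau = %d\n",
              x$selected$m, x$selected$r, x$selected$tau))
  invisible(x)
}
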