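#' Multiscale entropy parameters
#'
#' Bundle of the three multiscale sample entropy parameters: embedding
#' dimension `m`, similarity factor `r` and scale factor `tau`.
#'
#' `r` is interpreted as a fraction of the standard deviation of the
#' *original* (pre-coarse-graining) series, following the usual multiscale
#' entropy convention: the absolute tolerance used in template matching for
#' a series `x` is `r * sd(x)`.
#'
#' @param m Embedding dimension (positive integer; template length).
#' @param r Similarity factor, a positive fraction of the series standard
#'   deviation.
#' @param tau Scale factor (positive integer); the series is coarse-grained
#'   by non-overlapping averaging over windows of length `tau` before the
#'   sample entropy is computed.
#' @return An object of class `mse_params`.
#' @examples
#' mse_params(m = 1, r = 0.56, tau = 3)
#' @export
mse_params <- function(m = 1L, r = 0.56, tau = 3L) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop("'m' must be a single integer >= 1", call. = FALSE)
  if (length(tau) != 1L || is.na(tau) || tau < 1L)
    stop("'tau' must be a single integer >= 1", call. = FALSE)
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single positive number", call. = FALSE)
  structure(list(m = m, r = r, tau = tau), class = "mse_params")
}

#' @export
print.mse_params <- function(x, ...) {
  cat(sprintf("MSE parameters: m = %d, r = %g, tau = %d\n", x$m, x$r, x$tau))
  invisible(x)
}

#' Coarse-grain a time series
#'
#' Non-overlapping window averaging at scale `tau`: element `j` of the
#' result is the mean of `x[((j-1)*tau + 1):(j*tau)]`. The output has
#' length `floor(length(x)/tau)`; trailing remainder samples are discarded.
#' `tau = 1` returns `x` unchanged.
#'
#' @param x Numeric series.
#' @param tau Integer scale factor, `1 <= tau <= length(x)`.
#' @return Numeric vector of length `floor(length(x)/tau)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5, 6), tau = 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, tau) {
  x <- as.numeric(x)
  tau <- as.integer(tau)
  if (length(tau) != 1L || is.na(tau) || tau < 1L || tau > length(x))
    stop("'tau' must be a single integer with 1 <= tau <= length(x)",
         call. = FALSE)
  if (anyNA(x)) stop("'x' must not contain missing values", call. = FALSE)
  .coarse_grain_cpp(x, tau)
}

#' Sample entropy of a series
#'
#' Richman-Moorman sample entropy with an *absolute* matching tolerance:
#' templates of length `m` and `m + 1` are both drawn from start positions
#' `1..L-m`, pairs are compared by Chebyshev (max-absolute) distance with
#' self-matches excluded, and the entropy is `-log(A/B)` where `B` and `A`
#' are the ordered-pair match counts at lengths `m` and `m + 1`. A pair
#' matches when its distance is `<= r_abs`.
#'
#' If either count is zero the entropy is undefined and `NA` is returned
#' (an attribute `counts` always carries `A` and `B`); this occurs for
#' short series at small tolerances.
#'
#' @param y Numeric series (typically already coarse-grained).
#' @param m Embedding dimension, `length(y) - m >= 1`.
#' @param r_abs Absolute tolerance (already scaled by the sd of the
#'   original series; see [mse_value()]).
#' @return Sample entropy (non-negative number), or `NA_real_` when no
#'   template matches occurred, with attribute `counts = c(A =, B =)`.
#' @examples
#' sample_entropy(rep(1, 20), m = 2, r_abs = 0.2)  # constant series -> 0
#' @export
sample_entropy <- function(y, m, r_abs) {
  y <- as.numeric(y)
  m <- as.integer(m)
  if (length(y) - m < 1L)
    stop("series too short: need length(y) - m >= 1", call. = FALSE)
  if (length(r_abs) != 1L || !is.finite(r_abs) || r_abs <= 0)
    stop("'r_abs' must be a single positive number", call. = FALSE)
  cnt <- .sampen_counts(y, m, r_abs)
  B <- cnt[1L, 1L]; A <- cnt[2L, 1L]
  val <- if (A > 0 && B > 0) -log(A / B) else NA_real_
  structure(val, counts = c(A = A, B = B))
}

#' Multiscale entropy of a series at one parameter setting
#'
#' Computes the absolute tolerance `r_abs = params$r * sd(x)` on the
#' original series, coarse-grains at `params$tau`, and evaluates the sample
#' entropy at `params$m`. The sd is taken before coarse-graining so the
#' tolerance refers to the raw signal amplitude at every scale.
#'
#' @param x Numeric series.
#' @param params An [mse_params()] object.
#' @return Multiscale entropy value, or `NA_real_` when undefined (no
#'   template matches, or a constant series whose sd is zero).
#' @examples
#' set.seed(1)
#' mse_value(rnorm(246), mse_params(1, 0.56, 3))
#' @export
mse_value <- function(x, params) {
  stopifnot(inherits(params, "mse_params"))
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s)) return(NA_real_)
  if (s == 0) return(0)  # constant series: A = B, -log(1) = 0
  y <- coarse_grain(x, params$tau)
  if (length(y) - params$m < 1L)
    stop("series too short for m = ", params$m, " at tau = ", params$tau,
         call. = FALSE)
  as.numeric(sample_entropy(y, params$m, params$r * s))
}

#' Entropy matrix of a dataset at one parameter setting
#'
#' Evaluates [mse_value()] for every subject and region of a ROI
#' time-series dataset, producing the subjects x regions matrix that all
#' downstream group statistics operate on.
#'
#' @param ds A `roi_dataset` (see [generate_dataset()] or
#'   [read_roi_dataset()]).
#' @param params An [mse_params()] object.
#' @return An `entropy_matrix` object: list with `values` (subjects x
#'   regions numeric matrix, `NA` where the entropy is undefined),
#'   `undefined` (logical mask of the same shape), `params`, `labels` and
#'   `region_names`.
#' @export
entropy_matrix <- function(ds, params) {
  stopifnot(inherits(ds, "roi_dataset"), inherits(params, "mse_params"))
  ns <- dim(ds$data)[1L]; ng <- dim(ds$data)[2L]; nt <- dim(ds$data)[3L]
  if (nt %/% params$tau - params$m < 1L)
    stop("dataset timepoint count too small for these parameters",
         call. = FALSE)
  vals <- matrix(NA_real_, ns, ng,
                 dimnames = list(ds$subject_ids, ds$region_names))
  for (s in seq_len(ns))
    for (g in seq_len(ng))
      vals[s, g] <- mse_value(ds$data[s, g, ], params)
  structure(list(values = vals, undefined = is.na(vals), params = params,
                 labels = ds$labels, region_names = ds$region_names),
            class = "entropy_matrix")
}

#' @export
print.entropy_matrix <- function(x, ...) {
  cat(sprintf(
    "Entropy matrix: %d subjects x %d regions (m = %d, r = %g, tau = %d); %d undefined\n",
    nrow(x$values), ncol(x$values), x$params$m, x$params$r, x$params$tau,
    sum(x$undefined)))
  invisible(x)
}

# Entropy values for every (m, tau, r) grid cell in one pass per series.
# Returns a 4-d array [m, tau, r, flattened subject*region ... ] -- internal
# engine behind the parameter search; one .sampen_counts call covers the
# whole r vector for a fixed (series, m, tau).
entropy_grid <- function(ds, m_values, r_values, tau_values) {
  stopifnot(inherits(ds, "roi_dataset"))
  r_values <- sort(r_values)
  ns <- dim(ds$data)[1L]; ng <- dim(ds$data)[2L]
  out <- array(NA_real_,
               dim = c(length(m_values), length(tau_values), length(r_values),
                       ns, ng),
               dimnames = list(paste0("m", m_values), paste0("tau", tau_values),
                               sprintf("r%.2f", r_values), ds$subject_ids,
                               ds$region_names))
  for (s in seq_len(ns)) {
    for (g in seq_len(ng)) {
      x <- ds$data[s, g, ]
      sdx <- stats::sd(x)
      if (sdx == 0) { out[, , , s, g] <- 0; next }
      for (ti in seq_along(tau_values)) {
        y <- .coarse_grain_cpp(x, as.integer(tau_values[ti]))
        mmax <- max(m_values[m_values <= length(y) - 1L])
        if (length(mmax) == 0L) next
        cnt <- .sampen_counts_upto(y, as.integer(mmax), r_values * sdx)
        for (mi in seq_along(m_values)) {
          m <- as.integer(m_values[mi])
          if (m > mmax) next
          B <- cnt[2L * m - 1L, ]; A <- cnt[2L * m, ]
          v <- ifelse(A > 0 & B > 0, -log(A / B), NA_real_)
          out[mi, ti, , s, g] <- v
        }
      }
    }
  }
  out
}
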