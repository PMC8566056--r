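#' Select biomarker regions at fixed entropy parameters
#'
#' Regions whose intergroup entropy difference is significant at
#' `alpha_final` (two-sample t-test, uncorrected by default) are the
#' candidate functional biomarkers of the epileptogenic hemisphere. Their
#' unfolded AUCs are reported alongside. An empty set is allowed.
#'
#' @param mat An [entropy_matrix()] computed at the optimized parameters.
#' @param labels Binary subject labels (taken from `mat` when omitted).
#' @param alpha_final Selection threshold on the p-value (default 0.01;
#'   distinct from the 0.05 screening level of the counting stage).
#' @param welch Use Welch's t-test (default FALSE).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, replicating an uncorrected selection;
#'   `"BH"` gives a false-discovery-rate controlled variant).
#' @return A `biomarker_set`: list with `region_indices` (sorted, 1-based),
#'   `region_names`, `pvalues`, `aucs` (both over the selected regions),
#'   `all_pvalues`, `all_aucs`, `params`, `alpha_final`.
#' @export
select_biomarkers <- function(mat, labels = NULL, alpha_final = 0.01,
                              welch = FALSE, adjust = "none") {
  stopifnot(inherits(mat, "entropy_matrix"))
  if (is.null(labels)) labels <- mat$labels
  labels <- as.integer(labels)
  pv <- region_pvalues(mat, labels, welch = welch)
  pv_adj <- stats::p.adjust(pv, method = adjust)
  aucs <- .region_aucs(mat$values, labels)
  idx <- unname(which(!is.na(pv_adj) & pv_adj < alpha_final))
  structure(list(region_indices = idx,
                 region_names = mat$region_names[idx],
                 pvalues = pv_adj[idx], aucs = aucs[idx],
                 all_pvalues = pv_adj, all_aucs = aucs,
                 params = mat$params, alpha_final = alpha_final),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("Biomarker set: %d region(s) at p < %g (m = %d, r = %g, tau = %d)\n",
              length(x$region_indices), x$alpha_final,
              x$params$m, x$params$r, x$params$tau))
  if (length(x$region_indices))
    print(data.frame(index = x$region_indices, region = x$region_names,
                     p = signif(x$pvalues, 3), auc = round(x$aucs, 3),
                     row.names = NULL))
  invisible(x)
}

#' Biomarker report with group statistics and ROC curves
#'
#' One row per biomarker: region name, p-value, AUC, and per-group mean
#' and sd of the entropy values; the ROC curves are attached as an
#' attribute for serialization or plotting.
#'
#' @param bs A `biomarker_set` from [select_biomarkers()].
#' @param mat The [entropy_matrix()] the set was selected from.
#' @param labels Binary subject labels (taken from `mat` when omitted).
#' @return A data.frame (zero rows, with a warning, for an empty set) with
#'   attribute `roc` = named list of [roc_curve()] data.frames.
#' @export
biomarker_report <- function(bs, mat, labels = NULL) {
  stopifnot(inherits(bs, "biomarker_set"), inherits(mat, "entropy_matrix"))
  if (is.null(labels)) labels <- mat$labels
  labels <- as.integer(labels)
  if (length(bs$region_indices) == 0L) {
    warning("empty biomarker set: report has zero rows")
    out <- data.frame(region = character(0), p_value = numeric(0),
                      auc = numeric(0), mean_left = numeric(0),
                      sd_left = numeric(0), mean_right = numeric(0),
                      sd_right = numeric(0))
    attr(out, "roc") <- list()
    return(out)
  }
  rows <- lapply(seq_along(bs$region_indices), function(k) {
    g <- bs$region_indices[k]
    col <- mat$values[, g]
    data.frame(region = bs$region_names[k],
               p_value = bs$pvalues[k],
               auc = auc(col[!is.na(col)], labels[!is.na(col)]),
               mean_left = mean(col[labels == 1L], na.rm = TRUE),
               sd_left = stats::sd(col[labels == 1L][!is.na(col[labels == 1L])]),
               mean_right = mean(col[labels == 0L], na.rm = TRUE),
               sd_right = stats::sd(col[labels == 0L][!is.na(col[labels == 0L])]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "roc") <- stats::setNames(
    lapply(bs$region_indices, function(g) {
      col <- mat$values[, g]
      roc_curve(col[!is.na(col)], labels[!is.na(col)])
    }), bs$region_names)
  out
}
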