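#' AAL1 cortical region short names
#'
#' Returns short names for the first `n` regions of the AAL1 parcellation
#' (odd indices left, even right). For `n > 90` (or whenever the shipped
#' table does not cover `n`), remaining regions get synthetic `ROI-k`
#' names. The table is shipped for labelling convenience only; no
#' anatomical validation is implied.
#'
#' @param n Number of region names wanted (default 90).
#' @return Character vector of length `n`.
#' @export
aal90_names <- function(n = 90L) {
  n <- as.integer(n)
  path <- system.file("extdata", "aal90_names.tsv", package = "mselat")
  nm <- if (nzchar(path)) read.delim(path, stringsAsFactors = FALSE)$name
        else character(0)
  if (n <= length(nm)) nm[seq_len(n)]
  else c(nm, sprintf("ROI-%d", seq.int(length(nm) + 1L, n)))
}
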