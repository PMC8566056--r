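#' Read a per-subject ROI time-series matrix
#'
#' Expects a TSV with a header row (first column `region`, remaining
#' columns timepoint labels) and one row per region: region name followed
#' by the numeric series.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix regions x timepoints with region rownames.
#' @export
read_roi_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("parse error in ", path, ": need a region column plus timepoints",
         call. = FALSE)
  rn <- as.character(df[[1L]])
  if (anyDuplicated(rn))
    stop("parse error in ", path, ": duplicate region name '",
         rn[anyDuplicated(rn)], "'", call. = FALSE)
  num <- df[, -1L, drop = FALSE]
  for (j in seq_len(ncol(num))) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]) & num[[j]] != "NA")
    if (length(bad))
      stop(sprintf("parse error in %s: non-numeric cell at row %d, column %d",
                   path, bad[1L], j + 1L), call. = FALSE)
    num[[j]] <- v
  }
  m <- as.matrix(num)
  if (anyNA(m))
    stop("parse error in ", path, ": missing values are not allowed",
         call. = FALSE)
  rownames(m) <- rn
  m
}

#' Write a per-subject ROI time-series matrix
#'
#' Inverse of [read_roi_matrix()]: first column `region`, one column per
#' timepoint (`t1`, `t2`, ...). Full double precision is preserved so the
#' round-trip is bit-exact.
#'
#' @param mat Numeric regions x timepoints matrix with region rownames.
#' @param path Output TSV path.
#' @export
write_roi_matrix <- function(mat, path) {
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))  # lossless
  df <- data.frame(region = rownames(mat), chr, check.names = FALSE)
  colnames(df) <- c("region", paste0("t", seq_len(ncol(mat))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ROI dataset to a directory
#'
#' One TSV per subject (regions x timepoints), a `manifest.tsv`
#' (subject_id, file, label), and a `config.yaml` echo of the generating
#' configuration when the dataset carries one.
#'
#' @param ds A `roi_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_roi_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "roi_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.tsv", ds$subject_ids)
  for (s in seq_along(ds$subject_ids)) {
    m <- ds$data[s, , , drop = TRUE]
    rownames(m) <- ds$region_names
    write_roi_matrix(m, file.path(dir, files[s]))
  }
  manifest <- data.frame(subject_id = ds$subject_ids, file = files,
                         label = ds$labels)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- ds$provenance$config
  if (!is.null(cfg))
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a ROI dataset from a directory with a manifest
#'
#' @param dir Directory containing `manifest.tsv` and the per-subject TSVs
#'   written by [write_roi_dataset()].
#' @return A `roi_dataset`.
#' @export
read_roi_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("no manifest.tsv in ", dir, call. = FALSE)
  manifest <- read.delim(mpath, stringsAsFactors = FALSE)
  need <- c("subject_id", "file", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest.tsv must have columns subject_id, file, label",
         call. = FALSE)
  if (anyDuplicated(manifest$subject_id))
    stop("duplicate subject_id in manifest", call. = FALSE)
  if (!all(manifest$label %in% c(0L, 1L)))
    stop("manifest labels must be 0/1", call. = FALSE)
  mats <- lapply(file.path(dir, manifest$file), read_roi_matrix)
  dims <- vapply(mats, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("subject matrices disagree in shape", call. = FALSE)
  data <- array(NA_real_, dim = c(nrow(manifest), dims[1L, 1L], dims[2L, 1L]),
                dimnames = list(manifest$subject_id, rownames(mats[[1L]]),
                                NULL))
  for (s in seq_along(mats)) data[s, , ] <- mats[[s]]
  structure(list(data = data, labels = as.integer(manifest$label),
                 subject_ids = manifest$subject_id,
                 region_names = rownames(mats[[1L]]),
                 provenance = list(source = normalizePath(dir))),
            class = "roi_dataset")
}

#' Write an entropy matrix with a JSON parameter sidecar
#'
#' TSV (rows = subjects, columns = regions) plus `<path>.json` holding the
#' parameters and the undefined-entry count.
#'
#' @param mat An [entropy_matrix()].
#' @param path Output TSV path.
#' @export
write_entropy_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "entropy_matrix"))
  chr <- matrix(sprintf("%.17g", mat$values), nrow(mat$values),
                ncol(mat$values), dimnames = dimnames(mat$values))
  df <- data.frame(subject = rownames(mat$values), label = mat$labels,
                   chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(m = mat$params$m, r = mat$params$r,
                            tau = mat$params$tau,
                            n_undefined = sum(mat$undefined)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an entropy matrix written by [write_entropy_matrix()]
#'
#' @param path TSV path (the `<path>.json` sidecar must exist).
#' @return An [entropy_matrix()] object.
#' @export
read_entropy_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$subject
  structure(list(values = vals, undefined = is.na(vals),
                 params = mse_params(side$m, side$r, side$tau),
                 labels = as.integer(df$label),
                 region_names = colnames(vals)),
            class = "entropy_matrix")
}

#' Extract mean ROI time series from a 4D functional volume
#'
#' Projects a preprocessed 4D functional image onto an integer-labelled
#' 3D atlas on the *same* voxel grid: row `g` of the result is, per
#' volume, the mean over voxels carrying `region_ids[g]`. No resampling or
#' registration is performed; spatial alignment is the caller's
#' responsibility. Labels absent from the atlas yield a row of `NA` with a
#' warning.
#'
#' @param func_4d 4D numeric array, or a path to a NIfTI file (read with
#'   the RNifti package).
#' @param atlas_volume 3D integer array or NIfTI path, same spatial grid.
#' @param region_ids Integer labels to extract (default 1:90).
#' @param region_names Names for the rows (default the AAL1 short names).
#' @return Numeric matrix, regions x timepoints.
#' @export
extract_roi_timeseries <- function(func_4d, atlas_volume,
                                   region_ids = 1:90,
                                   region_names = aal90_names(length(region_ids))) {
  read_nii <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("reading NIfTI files requires the RNifti package",
             call. = FALSE)
      as.array(RNifti::readNifti(x))
    } else as.array(x)
  }
  func <- read_nii(func_4d)
  atlas <- read_nii(atlas_volume)
  if (length(dim(func)) != 4L)
    stop("functional volume must be 4D, got shape [",
         paste(dim(func), collapse = " x "), "]", call. = FALSE)
  if (length(dim(atlas)) != 3L)
    stop("atlas must be 3D, got shape [",
         paste(dim(atlas), collapse = " x "), "]", call. = FALSE)
  if (!identical(dim(func)[1:3], dim(atlas)))
    stop("grid mismatch: functional [",
         paste(dim(func)[1:3], collapse = " x "), "] vs atlas [",
         paste(dim(atlas), collapse = " x "), "]", call. = FALSE)
  stopifnot(length(region_ids) == length(region_names),
            all(region_ids != 0))
  nt <- dim(func)[4L]
  fmat <- matrix(func, ncol = nt)  # voxels x time
  out <- matrix(NA_real_, length(region_ids), nt,
                dimnames = list(region_names, NULL))
  for (g in seq_along(region_ids)) {
    vox <- which(atlas == region_ids[g])
    if (length(vox) == 0L) {
      warning("atlas label ", region_ids[g],
              " has no voxels; row set to NA")
      next
    }
    out[g, ] <- colMeans(fmat[vox, , drop = FALSE])
  }
  out
}
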