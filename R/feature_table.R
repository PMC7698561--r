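#' Construct a feature intensity table
#'
#' The central container of the pipeline: an LC-MS feature intensity matrix
#' (features in rows, samples in columns) with per-feature m/z, retention
#' time and ionization mode. A zero intensity encodes a missing value; any
#' other missingness token is rejected. Positive- and negative-mode features
#' live in one table, distinguished by `mode`.
#'
#' @param feature_ids character vector of unique feature identifiers.
#' @param mz numeric vector of m/z values (Thomson), one per feature.
#' @param rt numeric vector of retention times (minutes), one per feature.
#' @param mode character vector, `"positive"` or `"negative"`, per feature.
#' @param intensities numeric matrix, features x samples, non-negative;
#'   0 encodes missing before imputation.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   column of `intensities`.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(feature_ids, mz, rt, mode, intensities, sample_ids) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  x <- structure(
    list(
      feature_ids = as.character(feature_ids),
      mz = as.numeric(mz),
      rt = as.numeric(rt),
      mode = as.character(mode),
      intensities = intensities,
      sample_ids = as.character(sample_ids)
    ),
    class = "feature_table"
  )
  rownames(x$intensities) <- x$feature_ids
  colnames(x$intensities) <- x$sample_ids
  validate_feature_table(x)
  x
}

#' Validate a feature table
#'
#' Checks every structural invariant: dimension agreement, id uniqueness,
#' non-negative finite intensities, and valid ionization modes.
#'
#' @param x a `feature_table`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  p <- length(x$feature_ids)
  n <- length(x$sample_ids)
  if (length(x$mz) != p || length(x$rt) != p || length(x$mode) != p) {
    stop("mz, rt and mode must each have one entry per feature", call. = FALSE)
  }
  if (!all(dim(x$intensities) == c(p, n))) {
    stop(sprintf("intensity matrix is %d x %d, expected %d x %d",
                 nrow(x$intensities), ncol(x$intensities), p, n), call. = FALSE)
  }
  dup <- x$feature_ids[duplicated(x$feature_ids)]
  if (length(dup)) stop("duplicated feature_id: ", dup[1L], call. = FALSE)
  dup <- x$sample_ids[duplicated(x$sample_ids)]
  if (length(dup)) stop("duplicated sample_id: ", dup[1L], call. = FALSE)
  if (anyNA(x$intensities) || any(!is.finite(x$intensities))) {
    bad <- which(!is.finite(x$intensities), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite intensity at feature '%s', sample '%s' (only 0 encodes missingness)",
                 x$feature_ids[bad[1L]], x$sample_ids[bad[2L]]), call. = FALSE)
  }
  if (any(x$intensities < 0)) stop("negative intensities are not allowed", call. = FALSE)
  if (!all(x$mode %in% c("positive", "negative"))) {
    stop("mode must be 'positive' or 'negative'", call. = FALSE)
  }
  if (any(x$mz <= 0)) stop("m/z must be positive", call. = FALSE)
  if (any(x$rt < 0)) stop("retention time must be non-negative", call. = FALSE)
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%d positive / %d negative mode)\n",
              length(x$feature_ids), length(x$sample_ids),
              sum(x$mode == "positive"), sum(x$mode == "negative")))
  cat(sprintf("  m/z range [%.4f, %.4f], rt range [%.2f, %.2f] min, %.1f%% zero cells\n",
              min(x$mz), max(x$mz), min(x$rt), max(x$rt),
              100 * mean(x$intensities == 0)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table by features and/or samples
#'
#' @param x a `feature_table`.
#' @param features feature ids or indices (default all).
#' @param samples sample ids or indices (default all).
#' @return the subsetted `feature_table`.
#' @export
subset_features <- function(x, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_along(x$feature_ids) else {
    if (is.character(features)) match(features, x$feature_ids) else features
  }
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  if (anyNA(fi)) stop("unknown feature id", call. = FALSE)
  if (anyNA(si)) stop("unknown sample id", call. = FALSE)
  feature_table(x$feature_ids[fi], x$mz[fi], x$rt[fi], x$mode[fi],
                x$intensities[fi, si, drop = FALSE], x$sample_ids[si])
}

#' Validate sample metadata
#'
#' Sample metadata carries the study design: patient, condition
#' (before/during treatment or QC), replicate index and injection order.
#' QC samples are pooled quality controls injected at intervals; they have
#' no patient id.
#'
#' @param meta a data.frame with columns `sample_id`, `patient_id`,
#'   `condition` (one of `before`, `during`, `QC`), `replicate_index`,
#'   `injection_order`, `is_qc`.
#' @return `meta`, invisibly, if valid.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "patient_id", "condition", "replicate_index",
            "injection_order", "is_qc")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) stop("duplicated sample_id in metadata: ", dup[1L], call. = FALSE)
  if (!all(meta$condition %in% c("before", "during", "QC"))) {
    stop("condition must be one of 'before', 'during', 'QC'", call. = FALSE)
  }
  if (!identical(as.logical(meta$is_qc), meta$condition == "QC")) {
    stop("is_qc must hold exactly for condition == 'QC'", call. = FALSE)
  }
  study <- !meta$is_qc
  if (any(is.na(meta$patient_id[study]) | meta$patient_id[study] == "")) {
    stop("every non-QC sample needs a patient_id", call. = FALSE)
  }
  if (any(meta$replicate_index < 1)) stop("replicate_index must be >= 1", call. = FALSE)
  ord <- sort(as.integer(meta$injection_order))
  if (!identical(ord, seq_len(nrow(meta)))) {
    stop("injection_order must be a permutation of 1..n_samples", call. = FALSE)
  }
  invisible(meta)
}

# every table sample must be described by the metadata; the metadata may
# cover more samples (e.g. when preprocessing a training subset)
check_table_meta <- function(table, meta) {
  validate_feature_table(table)
  validate_sample_metadata(meta)
  only_t <- setdiff(table$sample_ids, meta$sample_id)
  if (length(only_t)) stop("sample in table but not metadata: ", only_t[1L], call. = FALSE)
  invisible(TRUE)
}

meta_for <- function(meta, sample_ids) {
  meta[match(sample_ids, meta$sample_id), , drop = FALSE]
}

# full-precision numeric formatting so read(write(x)) is bit-identical
fmt_full <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

#' Read a feature table and its sample metadata from TSV
#'
#' The feature table TSV has columns `feature_id, mz, rt, mode` followed by
#' one intensity column per sample; the metadata TSV has columns
#' `sample_id, patient_id, condition, replicate_index, injection_order,
#' is_qc`. Decimal separator is the dot. Missing intensities must be written
#' as 0 — any non-numeric token (including `NA`) is a hard error.
#'
#' @param path path to the feature table TSV.
#' @param meta_path path to the metadata TSV.
#' @return a list with elements `table` (a [feature_table]) and `meta`
#'   (a data.frame).
#' @export
read_feature_table <- function(path, meta_path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  fixed <- c("feature_id", "mz", "rt", "mode")
  miss <- setdiff(fixed, names(raw))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sample_cols <- setdiff(names(raw), fixed)
  ints <- matrix(NA_real_, nrow(raw), length(sample_cols))
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(raw[[sample_cols[j]]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric intensity '%s' at row %d, sample '%s' (only 0 encodes missingness)",
                   raw[[sample_cols[j]]][bad[1L]], bad[1L], sample_cols[j]),
           call. = FALSE)
    }
    ints[, j] <- v
  }
  meta <- utils::read.delim(meta_path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
  for (col in c("replicate_index", "injection_order")) {
    if (col %in% names(meta)) meta[[col]] <- as.integer(meta[[col]])
  }
  if ("is_qc" %in% names(meta)) meta$is_qc <- as.logical(meta$is_qc)
  if ("patient_id" %in% names(meta)) {
    meta$patient_id[meta$patient_id %in% c("", "NA")] <- NA_character_
  }
  tab <- feature_table(raw$feature_id, as.numeric(raw$mz), as.numeric(raw$rt),
                       raw$mode, ints, sample_cols)
  # name any sample-set mismatch before structural metadata validation,
  # so the offending sample is reported directly
  only_t <- setdiff(tab$sample_ids, meta$sample_id)
  if (length(only_t)) stop("sample in table but not metadata: ", only_t[1L],
                           call. = FALSE)
  only_m <- setdiff(meta$sample_id, tab$sample_ids)
  if (length(only_m)) stop("sample in metadata but not table: ", only_m[1L],
                           call. = FALSE)
  check_table_meta(tab, meta)
  list(table = tab, meta = meta)
}

#' Write a feature table and its metadata to TSV
#'
#' Values are printed at full precision so that
#' `read_feature_table(write_feature_table(x))` reproduces `x` bit-exactly;
#' m/z is stored at full precision (always at least 4 decimals).
#'
#' @param table a [feature_table].
#' @param meta the matching metadata data.frame.
#' @param path output path for the feature table TSV.
#' @param meta_path output path for the metadata TSV.
#' @return invisibly, the two paths.
#' @export
write_feature_table <- function(table, meta, path, meta_path) {
  check_table_meta(table, meta)
  df <- data.frame(feature_id = table$feature_ids,
                   mz = fmt_full(table$mz),
                   rt = fmt_full(table$rt),
                   mode = table$mode,
                   stringsAsFactors = FALSE, check.names = FALSE)
  ints <- apply(table$intensities, 2L, fmt_full)
  if (length(table$feature_ids) == 1L) ints <- matrix(ints, nrow = 1L)
  if (length(table$feature_ids) == 0L) {
    ints <- matrix(character(0), 0L, length(table$sample_ids))
  }
  colnames(ints) <- table$sample_ids
  utils::write.table(cbind(df, ints), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m <- meta
  m$patient_id[is.na(m$patient_id)] <- "NA"
  utils::write.table(m, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Export the 4-column annotation input
#'
#' Writes the Mummichog-style input (`mz`, `rt`, `p_value`, `mode`), one row
#' per feature in table order. The p-values may come from the univariate
#' route or from sMC F-values converted upstream.
#'
#' @param table a [feature_table].
#' @param pvalues numeric vector, one p-value in (0, 1] per feature.
#' @param path output TSV path; if `NULL`, the data.frame is returned only.
#' @return invisibly (or visibly when `path` is `NULL`) the exported
#'   data.frame.
#' @export
export_mummichog_input <- function(table, pvalues, path = NULL) {
  validate_feature_table(table)
  if (length(pvalues) != length(table$feature_ids)) {
    stop(sprintf("got %d p-values for %d features",
                 length(pvalues), length(table$feature_ids)), call. = FALSE)
  }
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must be finite and in (0, 1]", call. = FALSE)
  }
  out <- data.frame(mz = table$mz, rt = table$rt, p_value = pvalues,
                    mode = table$mode, stringsAsFactors = FALSE)
  rownames(out) <- table$feature_ids
  if (!is.null(path)) {
    utils::write.table(data.frame(mz = fmt_full(out$mz), rt = fmt_full(out$rt),
                                  p_value = fmt_full(out$p_value),
                                  mode = out$mode),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
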