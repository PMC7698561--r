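# Small deterministic fixtures shared across test files.

tiny_table <- function(n_feat = 3, n_samp = 4, seed = 1, mode = NULL) {
  set.seed(seed)
  if (is.null(mode)) mode <- rep_len(c("positive", "negative"), n_feat)
  feature_table(
    feature_ids = sprintf("FT%02d", seq_len(n_feat)),
    mz = runif(n_feat, 80, 600),
    rt = runif(n_feat, 1, 12),
    mode = mode,
    intensities = matrix(exp(rnorm(n_feat * n_samp, 10, 0.5)), n_feat, n_samp),
    sample_ids = sprintf("S%02d", seq_len(n_samp))
  )
}

tiny_meta <- function(sample_ids, n_qc = 0) {
  n <- length(sample_ids)
  study <- n - n_qc
  data.frame(
    sample_id = sample_ids,
    patient_id = c(sprintf("P%02d", rep(seq_len(ceiling(study / 2)), each = 2))[seq_len(study)],
                   rep(NA_character_, n_qc)),
    condition = c(rep_len(c("before", "during"), study), rep("QC", n_qc)),
    replicate_index = rep(1L, n),
    injection_order = seq_len(n),
    is_qc = c(rep(FALSE, study), rep(TRUE, n_qc)),
    stringsAsFactors = FALSE
  )
}

# a reduced cohort that still has >= 5 QCs (10 patients -> 40 study samples)
small_cohort <- function(seed = 1, n_features = 200, ...) {
  generate_cohort(cohort_config(n_patients = 10L, n_features = n_features,
                                n_proxy_features = 5L, seed = seed, ...))
}

# paired duplicate-mean matrices (before, during) on the glog scale
paired_matrices <- function(pp, meta) {
  gt <- pp$table
  gt$intensities <- pp$glog[, gt$sample_ids]
  avg <- average_duplicates(gt, meta)
  pats <- unique(avg$meta$patient_id)
  list(before = avg$table$intensities[, paste0(pats, "_before"), drop = FALSE],
       during = avg$table$intensities[, paste0(pats, "_during"), drop = FALSE])
}

# two-class toy matrix with informative columns
toy_xy <- function(n = 24, p = 6, informative = 1, noise = 0.3, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(informative)) X[, j] <- y + rnorm(n, 0, noise)
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, y = y)
}

# memoized default cohort + preprocessing (shared by the acceptance blocks)
.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$coh)) {
    .fixture_cache$coh <- generate_cohort(cohort_config(seed = 1))
  }
  .fixture_cache$coh
}

default_preprocessed <- function() {
  if (is.null(.fixture_cache$pp)) {
    .fixture_cache$pp <- preprocess_full(default_cohort()$table,
                                         default_cohort()$meta)
  }
  .fixture_cache$pp
}

# univariate p-values of the default cohort (duplicate means, glog scale)
default_wilcoxon_p <- function() {
  if (is.null(.fixture_cache$pv)) {
    coh <- default_cohort()
    pm <- paired_matrices(default_preprocessed(), coh$meta)
    .fixture_cache$pv <- wilcoxon_paired(pm$before, pm$during)
  }
  .fixture_cache$pv
}
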