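test_that("default design reproduces the paired-cohort layout", {
  coh <- generate_cohort(cohort_config(seed = 1))
  meta <- coh$meta
  study <- meta[!meta$is_qc, ]
  expect_equal(nrow(study), 14 * 2 * 2)
  expect_equal(length(unique(study$patient_id)), 14L)
  # a QC after every 9th or 10th study injection, alternating
  qc_orders <- meta$injection_order[meta$is_qc]
  gaps <- diff(c(0, qc_orders)) - 1   # study samples between QCs
  expect_true(all(gaps %in% c(9, 10) | seq_along(gaps) == length(gaps)))
  expect_equal(gaps[1:4], c(9, 10, 9, 10))
  # injection order is a permutation
  expect_setequal(meta$injection_order, seq_len(nrow(meta)))
  validate_sample_metadata(meta)
  validate_feature_table(coh$table)
})

test_that("same seed gives a bit-identical cohort, different seed does not", {
  a <- generate_cohort(cohort_config(seed = 7))
  b <- generate_cohort(cohort_config(seed = 7))
  c <- generate_cohort(cohort_config(seed = 8))
  expect_identical(a$table, b$table)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$responsive, b$truth$responsive)
  expect_false(identical(a$table$intensities, c$table$intensities))
})

test_that("noise-free limit: duplicates identical, fold changes exact", {
  coh <- generate_cohort(cohort_config(seed = 2, noise_cv = 0,
                                       drift_amplitude = 0, missing_rate = 0))
  x <- coh$table$intensities
  m <- coh$meta
  study <- m[!m$is_qc, ]
  for (key in unique(paste(study$patient_id, study$condition))) {
    ids <- study$sample_id[paste(study$patient_id, study$condition) == key]
    expect_equal(x[, ids[1]], x[, ids[2]])
  }
  fc <- compute_fold_changes(
    subset_features(coh$table, features = coh$truth$responsive$feature_id),
    coh$meta)
  expect_equal(unname(fc), coh$truth$responsive$fold_change, tolerance = 1e-12)
})

test_that("realized fold changes and block correlations meet the generative contract", {
  coh <- generate_cohort(cohort_config())   # default study conditions
  fc <- compute_fold_changes(
    subset_features(coh$table, features = coh$truth$responsive$feature_id),
    coh$meta)
  expect_true(all(abs(fc / coh$truth$responsive$fold_change - 1) <= 0.25))

  target <- coh$truth$config$block_specs[[1]]$cor
  block_cor_min <- function(c) {
    ids <- c$truth$blocks[[1]]
    study <- c$meta$sample_id[!c$meta$is_qc]
    x <- c$table$intensities[ids, study]
    x[x == 0] <- NA
    cc <- cor(t(log(x)), use = "pairwise.complete.obs")
    c(min = min(cc), mean = mean(cc[lower.tri(cc)]))
  }
  expect_gte(block_cor_min(coh)["min"], target - 0.1)
  # and on average across further seeds
  more <- vapply(2:4, function(s)
    block_cor_min(generate_cohort(cohort_config(seed = s)))["mean"], numeric(1))
  expect_true(all(more >= target - 0.1))
})

test_that("QC replicates are tighter than study samples and zeros sit in the low tail", {
  coh <- generate_cohort(cohort_config(seed = 3))
  x <- coh$table$intensities
  m <- coh$meta
  g <- glog_transform(x, 100)
  ok <- x[, m$sample_id[m$is_qc]] > 0
  qc_sd <- apply(g[, m$sample_id[m$is_qc]], 1, sd)
  st_sd <- apply(g[, m$sample_id[!m$is_qc]], 1, sd)
  # QC spread is purely technical; study samples add biology. The per-
  # feature QC sd is estimated from ~6 injections, so compare in aggregate.
  expect_gt(mean(st_sd), mean(qc_sd))
  expect_gt(mean(st_sd >= qc_sd), 0.6)

  # zero probability decreases with feature intensity
  zr <- rowMeans(x == 0)
  med <- apply(x, 1, function(v) median(v[v > 0]))
  keep <- !is.na(med)
  expect_lt(cor(rank(med[keep]), rank(zr[keep])), -0.3)
  lo <- med < quantile(med, 0.2, na.rm = TRUE)
  hi <- med > quantile(med, 0.8, na.rm = TRUE)
  expect_gt(mean(zr[lo], na.rm = TRUE), mean(zr[hi], na.rm = TRUE))
})

test_that("the spiked block carries the minimal attainable Wilcoxon p at n = 14", {
  coh <- generate_cohort(cohort_config(seed = 5))
  avg <- average_duplicates(coh$table, coh$meta)
  pats <- unique(avg$meta$patient_id)
  B <- avg$table$intensities[coh$truth$blocks[[1]], paste0(pats, "_before")]
  D <- avg$table$intensities[coh$truth$blocks[[1]], paste0(pats, "_during")]
  p <- wilcoxon_paired(B, D)
  expect_true(all(p == 2 / 2^14))
})

test_that("recovery metrics follow their definitions", {
  coh <- small_cohort(seed = 1, n_features = 60)
  truth <- coh$truth
  resp <- truth$responsive$feature_id
  r <- evaluate_recovery(resp, truth)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$fdp, 0)
  r0 <- evaluate_recovery(character(0), truth)
  expect_equal(r0$sensitivity, 0)
  rp <- evaluate_recovery(truth$proxy_ids, truth)
  expect_equal(rp$sensitivity, 0)
  expect_equal(rp$n_proxy, length(truth$proxy_ids))
  expect_equal(rp$fdp, 1)
  expect_error(evaluate_recovery("NOPE", truth), "unknown feature id")
})

test_that("infeasible block configurations are rejected", {
  expect_error(cohort_config(n_features = 5L), "exceed n_features")
  expect_error(cohort_config(block_specs = list(list(size = 2L, cor = 0.7,
                                                     fold_change = -1))),
               "fold changes")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
})
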