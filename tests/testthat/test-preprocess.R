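make_filter_fixture <- function() {
  # 6 features x (10 study + 2 QC) samples, engineered against each rule
  n_study <- 10; n_qc <- 2
  x <- matrix(1000, 6, n_study + n_qc)
  x[1, 1:2] <- 0            # 20% zeros among study samples -> retained
  x[2, 1:3] <- 0            # 30% zeros -> removed
  x[3, 11] <- 0             # a zero in a QC sample -> removed
  tab <- feature_table(paste0("F", 1:6),
                       mz = c(100, 150, 200, 69.99, 70.00, 300),
                       rt = c(5, 5, 5, 5, 5, 16.01),
                       mode = rep("positive", 6),
                       intensities = x,
                       sample_ids = sprintf("S%02d", 1:12))
  list(table = tab, meta = tiny_meta(tab$sample_ids, n_qc = 2))
}

test_that("feature filters use strict boundaries and report per-rule counts", {
  fx <- make_filter_fixture()
  out <- filter_features(fx$table, fx$meta)
  expect_setequal(out$table$feature_ids, c("F1", "F5"))
  expect_equal(out$report$removed[out$report$rule == "zero_fraction"], 1)
  expect_equal(out$report$removed[out$report$rule == "qc_zero"], 1)
  expect_equal(out$report$removed[out$report$rule == "mz_window"], 1)  # 69.99 only
  expect_equal(out$report$removed[out$report$rule == "rt_window"], 1)  # 16.01

  no_qc <- subset_features(fx$table, samples = 1:10)
  expect_error(filter_features(no_qc, fx$meta), "QC")
})

test_that("QC-SVR correction is near-identity without drift and shrinks QC CV under drift", {
  coh <- small_cohort(seed = 4, n_features = 40, drift_amplitude = 0,
                      missing_rate = 0)
  filt <- filter_features(coh$table, coh$meta)$table
  corr <- qc_svr_correct(filt, coh$meta)
  rel <- abs(corr$table$intensities / filt$intensities - 1)
  expect_lt(median(rel), 0.01)

  drifted <- small_cohort(seed = 4, n_features = 40, drift_amplitude = 0.3,
                          missing_rate = 0)
  dfilt <- filter_features(drifted$table, drifted$meta)$table
  dcorr <- qc_svr_correct(dfilt, drifted$meta)
  qc_ids <- drifted$meta$sample_id[drifted$meta$is_qc]
  cv <- function(m) apply(m[, qc_ids], 1, function(v) sd(v) / mean(v))
  expect_lt(mean(cv(dcorr$table$intensities)), mean(cv(dfilt$intensities)))

  # fewer than 5 QCs: warn, identity
  few <- subset_features(dfilt, samples = c(
    drifted$meta$sample_id[!drifted$meta$is_qc], qc_ids[1:3]))
  expect_warning(out <- qc_svr_correct(few, drifted$meta), "skipped")
  expect_identical(out$table$intensities, few$intensities)
})

test_that("PQN quotients follow their closed form and concentrate near 1", {
  coh <- small_cohort(seed = 5, n_features = 50, missing_rate = 0)
  filt <- filter_features(coh$table, coh$meta)$table
  m <- coh$meta
  qc_ids <- m$sample_id[m$is_qc]
  ref <- apply(filt$intensities[, qc_ids], 1, median)

  # a sample equal to the reference has quotient 1; 2x reference has quotient 2
  tab2 <- filt
  tab2$intensities[, 1] <- ref
  tab2$intensities[, 2] <- 2 * ref
  out <- pqn_normalize(tab2, m)
  expect_equal(unname(out$quotients[1]), 1)
  expect_equal(unname(out$quotients[2]), 2)
  expect_equal(out$table$intensities[, 2], ref, ignore_attr = TRUE)

  # generator-default samples: most quotients close to 1
  q <- pqn_normalize(filt, m)$quotients
  expect_gt(mean(abs(log(q)) < log(1.25)), 0.9)

  bad <- filt; bad$intensities[3, qc_ids] <- 0
  expect_error(pqn_normalize(bad, m), "reference contains 0")
})

test_that("KNN imputation matches a brute-force neighbor oracle and stays positive", {
  tab <- tiny_table(n_feat = 2, n_samp = 3, seed = 2)
  tab$intensities[1, ] <- c(5, 5, 5)
  tab$intensities[2, ] <- c(7, 7, 7)
  expect_identical(knn_impute(tab, k = 2), tab)  # no zeros -> identity

  tab$intensities[1, 2] <- 0   # three identical samples, one zeroed cell
  imp <- knn_impute(tab, k = 2)
  expect_equal(imp$intensities[1, 2], 5)

  # random 5 x 6 table with several zeros, k = 2, vs exhaustive oracle
  set.seed(9)
  x <- matrix(exp(rnorm(30, 3, 0.5)), 5, 6)
  x[cbind(c(1, 3, 4), c(2, 5, 2))] <- 0
  tab5 <- feature_table(paste0("F", 1:5), mz = 100 + 1:5, rt = rep(5, 5),
                        mode = rep("positive", 5), intensities = x,
                        sample_ids = paste0("S", 1:6))
  imp5 <- knn_impute(tab5, k = 2)
  oracle <- function(x, j, i, k) {
    xi <- x[, i]
    d <- sapply(seq_len(ncol(x)), function(s) {
      if (s == i) return(Inf)
      sh <- xi > 0 & x[, s] > 0
      if (!any(sh)) return(Inf)
      sqrt(sum((xi[sh] - x[sh, s])^2) / sum(sh))
    })
    ok <- which(x[j, ] > 0 & is.finite(d))
    mean(x[j, ok[order(d[ok])][seq_len(min(k, length(ok)))]])
  }
  for (cell in list(c(1, 2), c(3, 5), c(4, 2))) {
    expect_equal(imp5$intensities[cell[1], cell[2]],
                 oracle(x, cell[1], cell[2], 2))
  }
  expect_true(all(imp5$intensities > 0))

  dead <- tab5; dead$intensities[, 3] <- 0
  expect_error(knn_impute(dead, k = 2), "no observed values")
})

test_that("glog transform is monotone, reduces to ln at lambda 0, and lambda is tuned on QCs", {
  x <- sort(runif(50, 0.1, 1000))
  expect_equal(glog_transform(x, 0), log(x))
  for (lam in c(0, 1, 1e4)) {
    expect_true(all(diff(glog_transform(x, lam)) > 0))
  }

  # QC replicates with mixed additive + multiplicative noise: the tuned
  # lambda beats the grid endpoints on the profile likelihood objective
  set.seed(11)
  coh <- small_cohort(seed = 11, n_features = 80, missing_rate = 0)
  filt <- filter_features(coh$table, coh$meta)$table
  qc_ids <- coh$meta$sample_id[coh$meta$is_qc]
  qx <- filt$intensities[, qc_ids] +
    matrix(rnorm(length(qc_ids) * nrow(filt$intensities), 0, 500),
           nrow(filt$intensities))
  filt$intensities[, qc_ids] <- pmax(qx, 1)
  lam <- glog_fit_lambda(filt, coh$meta)
  expect_gt(lam, 0)
  obj <- function(l) metaboselect:::glog_objective(l, filt$intensities[, qc_ids])
  scale2 <- median(filt$intensities[, qc_ids])^2
  expect_lt(obj(lam), obj(scale2 * 1e-8))
  expect_lt(obj(lam), obj(scale2 * 1e4))

  few <- subset_features(filt, samples = c(
    coh$meta$sample_id[!coh$meta$is_qc], qc_ids[1:2]))
  expect_error(glog_fit_lambda(few, coh$meta), "explicit lambda")
})

test_that("centering uses training means only", {
  set.seed(3)
  x <- matrix(rnorm(50), 5, 10)
  train <- 1:6
  ctr <- mean_center(x[, train])
  expect_true(all(abs(rowMeans(ctr$x)) < 1e-10))
  held <- sweep(x[, -train], 1, ctr$means, "-")
  own <- mean_center(x[, -train])$x
  expect_false(isTRUE(all.equal(held, own)))
})

test_that("duplicate averaging collapses replicates and drops QCs", {
  coh <- small_cohort(seed = 6, n_features = 30)
  avg <- average_duplicates(coh$table, coh$meta)
  expect_equal(ncol(avg$table$intensities), 10 * 2)
  expect_false(any(avg$meta$condition == "QC"))
  # (4, 6) -> 5 on an engineered pair
  tab <- tiny_table(n_feat = 1, n_samp = 4, seed = 1)
  tab$intensities[1, ] <- c(4, 6, 3, 9)
  meta <- data.frame(sample_id = tab$sample_ids,
                     patient_id = c("P1", "P1", "P2", "P2"),
                     condition = c("before", "before", "before", "before"),
                     replicate_index = c(1L, 2L, 1L, 2L),
                     injection_order = 1:4, is_qc = FALSE,
                     stringsAsFactors = FALSE)
  out <- average_duplicates(tab, meta)
  expect_equal(unname(out$table$intensities[1, "P1_before"]), 5)
  # single replicate is a passthrough
  single <- subset_features(tab, samples = c(1, 3))
  out1 <- average_duplicates(single, meta)
  expect_equal(unname(out1$table$intensities[1, ]), c(4, 3))
})

test_that("full-cohort defaults: 14 x 2 x 2 duplicates average to 28 columns", {
  coh <- generate_cohort(cohort_config(seed = 9, n_features = 50L,
                                       n_proxy_features = 2L,
                                       block_specs = list(list(
                                         size = 3L, cor = 0.7,
                                         fold_change = 4, direction = 1))))
  avg <- average_duplicates(coh$table, coh$meta)
  expect_equal(ncol(avg$table$intensities), 28L)
})

test_that("preprocessing state never consults held-out samples and applies deterministically", {
  coh <- small_cohort(seed = 8, n_features = 120)
  meta <- coh$meta
  study <- meta$sample_id[!meta$is_qc]
  test_pat <- unique(meta$patient_id[!meta$is_qc])[1:2]
  train_ids <- study[!meta$patient_id[match(study, meta$sample_id)] %in% test_pat]
  test_ids <- setdiff(study, train_ids)

  state1 <- preprocess_fit(coh$table, meta, train_ids)
  perturbed <- coh$table
  perturbed$intensities[, test_ids] <- perturbed$intensities[, test_ids] * 5
  state2 <- preprocess_fit(perturbed, meta, train_ids)
  expect_identical(state1, state2)

  # deterministic application: same state, same output
  a <- preprocess_apply(state1, coh$table, meta, test_ids)
  b <- preprocess_apply(state1, coh$table, meta, test_ids)
  expect_identical(a, b)
  # training columns are centered to zero mean per feature
  tr <- preprocess_apply(state1, coh$table, meta, train_ids)
  expect_true(all(abs(rowMeans(tr$x)) < 1e-10))
  expect_true(all(tr$raw > 0))
})
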