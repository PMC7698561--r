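#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain: feature filters (missingness,
#' m/z and retention-time windows), QC-SVR drift correction, KNN
#' imputation and the glog transform.
#'
#' @param max_zero_fraction features with a zero fraction over study
#'   samples strictly greater than this are removed (default 0.20).
#' @param mz_min,mz_max m/z window; features strictly outside are removed
#'   (defaults 70 and 700).
#' @param rt_min,rt_max retention-time window in minutes (defaults 0.4
#'   and 16).
#' @param knn_k neighbors for KNN imputation (default 10).
#' @param glog_lambda `"optimize"` (default) to tune the glog parameter on
#'   the QC samples, or an explicit positive value.
#' @param svr_cost regularization constant of the QC support-vector
#'   regression (default 1).
#' @param svr_epsilon_factor epsilon of the SVR tube, as a multiple of the
#'   median absolute deviation of the feature's QC intensities
#'   (default 0.1).
#' @param min_qc minimum number of QC samples required for drift
#'   correction (default 5; with fewer, correction is skipped with a
#'   warning).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(max_zero_fraction = 0.20,
                              mz_min = 70, mz_max = 700,
                              rt_min = 0.4, rt_max = 16,
                              knn_k = 10L,
                              glog_lambda = "optimize",
                              svr_cost = 1,
                              svr_epsilon_factor = 0.1,
                              min_qc = 5L) {
  stopifnot(max_zero_fraction >= 0, max_zero_fraction < 1,
            mz_min < mz_max, rt_min < rt_max, knn_k >= 1)
  structure(as.list(environment()), class = "preprocess_config")
}

#' Filter features by missingness, QC zeros, m/z and retention time
#'
#' Removal rules, applied in order: (1) zero fraction over study samples
#' strictly greater than `max_zero_fraction`; (2) any zero in a QC sample;
#' (3) m/z strictly below `mz_min` or above `mz_max`; (4) retention time
#' strictly below `rt_min` or above `rt_max`. All boundaries are strict
#' ("more than 20%", "lower than 70"): a feature with exactly 20% zeros,
#' or m/z exactly 70, is retained.
#'
#' @param table a [feature_table].
#' @param meta matching sample metadata.
#' @param config a [preprocess_config()].
#' @return a list with `table` (filtered) and `report` (a data.frame of
#'   counts removed per rule).
#' @export
filter_features <- function(table, meta, config = preprocess_config()) {
  check_table_meta(table, meta)
  m <- meta_for(meta, table$sample_ids)
  if (!any(m$is_qc)) stop("no QC samples present; the QC-zero filter requires QCs",
                          call. = FALSE)
  x <- table$intensities
  study <- !m$is_qc
  keep <- rep(TRUE, nrow(x))
  zf <- rowMeans(x[, study, drop = FALSE] == 0)
  r1 <- keep & zf > config$max_zero_fraction
  keep <- keep & !r1
  qz <- rowSums(x[, m$is_qc, drop = FALSE] == 0) > 0
  r2 <- keep & qz
  keep <- keep & !r2
  r3 <- keep & (table$mz < config$mz_min | table$mz > config$mz_max)
  keep <- keep & !r3
  r4 <- keep & (table$rt < config$rt_min | table$rt > config$rt_max)
  keep <- keep & !r4
  report <- data.frame(
    rule = c("zero_fraction", "qc_zero", "mz_window", "rt_window"),
    removed = c(sum(r1), sum(r2), sum(r3), sum(r4)),
    stringsAsFactors = FALSE
  )
  list(table = subset_features(table, features = which(keep)), report = report)
}

# Fit per-feature QC-SVR drift curves: radial-basis SVR of QC intensity on
# injection order, evaluated at every injection order of the run.
fit_drift_curves <- function(x_qc, qc_orders, all_orders, config) {
  p <- nrow(x_qc)
  f <- matrix(1, p, length(all_orders))
  gamma <- 1 / max(diff(range(all_orders)), 1)
  for (j in seq_len(p)) {
    y <- x_qc[j, ]
    # svm() standardizes y internally, so the epsilon tube (a multiple of
    # the QC MAD) is expressed in units of sd(y)
    eps <- config$svr_epsilon_factor * stats::mad(y) / max(stats::sd(y), 1e-12)
    if (!is.finite(eps) || eps <= 0) eps <- 0.1
    pred <- tryCatch({
      fit <- e1071::svm(x = matrix(qc_orders, ncol = 1), y = y,
                        kernel = "radial", gamma = gamma,
                        cost = config$svr_cost, epsilon = eps, scale = TRUE)
      as.numeric(stats::predict(fit, matrix(all_orders, ncol = 1)))
    }, error = function(e) {
      # e.g. all QC points inside the epsilon tube: flat trend, no drift
      rep(stats::median(y), length(all_orders))
    })
    # guard against non-positive extrapolation
    f[j, ] <- pmax(pred, 0.05 * stats::median(y))
  }
  f
}

#' QC-SVR intra-batch drift correction
#'
#' Per feature, a radial-basis support-vector regression of the QC
#' intensities on injection order gives a smooth drift curve f(order);
#' every intensity is rescaled by median(QC)/f(order). Zeros are left
#' untouched. With fewer than `min_qc` QC samples the correction is
#' skipped with a warning (identity).
#'
#' @param table a [feature_table] (after filtering).
#' @param meta matching metadata.
#' @param config a [preprocess_config()].
#' @return list with `table` (corrected), `drift` (features x injections
#'   drift-curve matrix, scaled so 1 = no drift) and `qc_median`.
#' @export
qc_svr_correct <- function(table, meta, config = preprocess_config()) {
  check_table_meta(table, meta)
  m <- meta_for(meta, table$sample_ids)
  qc <- which(m$is_qc)
  all_orders <- seq_len(max(meta$injection_order))
  if (length(qc) < config$min_qc) {
    warning(sprintf("only %d QC samples (< %d): drift correction skipped",
                    length(qc), config$min_qc))
    d <- matrix(1, nrow(table$intensities), length(all_orders))
    return(list(table = table, drift = d,
                qc_median = apply(table$intensities[, qc, drop = FALSE], 1, stats::median)))
  }
  x <- table$intensities
  # curves are evaluated over the whole run so the state transfers to
  # held-out samples at any injection order
  f <- fit_drift_curves(x[, qc, drop = FALSE], m$injection_order[qc],
                        all_orders, config)
  med <- apply(x[, qc, drop = FALSE], 1, stats::median)
  corr <- x * (med / f[, m$injection_order, drop = FALSE])
  corr[x == 0] <- 0
  out <- table
  out$intensities <- corr
  validate_feature_table(out)
  list(table = out, drift = f / med, qc_median = med)
}

#' Probabilistic quotient normalization against the QC median spectrum
#'
#' The reference spectrum is the per-feature median over QC samples; each
#' sample's dilution quotient is the median over its non-zero features of
#' intensity/reference, and the sample is divided by that quotient. A
#' sample identical to the reference has quotient 1.
#'
#' @param table a [feature_table] (QC-zero features must already be
#'   filtered: a zero in the reference is an error).
#' @param meta matching metadata.
#' @param reference optional externally fitted reference spectrum (used
#'   when applying a training-set state to held-out samples).
#' @return list with `table` (normalized), `quotients` (per sample) and
#'   `reference`.
#' @export
pqn_normalize <- function(table, meta, reference = NULL) {
  check_table_meta(table, meta)
  m <- meta_for(meta, table$sample_ids)
  x <- table$intensities
  if (is.null(reference)) {
    if (!any(m$is_qc)) stop("no QC samples to build the PQN reference", call. = FALSE)
    reference <- apply(x[, m$is_qc, drop = FALSE], 1, stats::median)
  }
  if (any(reference == 0)) {
    stop("PQN reference contains 0; filter QC-zero features first", call. = FALSE)
  }
  q <- vapply(seq_len(ncol(x)), function(i) {
    obs <- x[, i] > 0
    if (!any(obs)) stop("sample '", table$sample_ids[i],
                        "' has no observed values", call. = FALSE)
    stats::median(x[obs, i] / reference[obs])
  }, numeric(1))
  out <- table
  out$intensities <- sweep(x, 2L, q, "/")
  out$intensities[x == 0] <- 0
  list(table = out, quotients = stats::setNames(q, table$sample_ids),
       reference = reference)
}

#' KNN imputation of zero intensities
#'
#' Neighbors are samples (column vectors). The distance between two
#' samples is the Euclidean distance over features observed (non-zero) in
#' both, scaled by the number of shared features; each zero is replaced by
#' the average of the k nearest donor samples that observed that feature.
#' k is truncated to the available donors. The output is strictly
#' positive.
#'
#' @param table a [feature_table] after filtering (so every feature has
#'   enough observed values).
#' @param k number of neighbors (the study uses 10).
#' @param donors optional matrix of donor sample columns (same features)
#'   with their sample ids as colnames; defaults to the table itself.
#'   Used to impute held-out samples from training donors only.
#' @return the imputed [feature_table].
#' @export
knn_impute <- function(table, k = 10L, donors = NULL) {
  validate_feature_table(table)
  x <- table$intensities
  if (is.null(donors)) donors <- x
  if (!all(dim(donors)[1L] == nrow(x))) stop("donor matrix feature mismatch", call. = FALSE)
  if (!any(x == 0)) return(table)
  dobs <- donors > 0
  for (i in which(colSums(x == 0) > 0)) {
    xi <- x[, i]
    obs_i <- xi > 0
    if (!any(obs_i)) stop("sample '", table$sample_ids[i],
                          "' has no observed values", call. = FALSE)
    self <- colnames(donors) == table$sample_ids[i]
    dist_i <- vapply(seq_len(ncol(donors)), function(d) {
      if (self[d]) return(Inf)
      shared <- obs_i & dobs[, d]
      if (!any(shared)) return(Inf)
      sqrt(sum((xi[shared] - donors[shared, d])^2) / sum(shared))
    }, numeric(1))
    for (j in which(xi == 0)) {
      ok <- which(dobs[j, ] & is.finite(dist_i))
      if (!length(ok)) stop("no donor observed feature '",
                            table$feature_ids[j], "'", call. = FALSE)
      kk <- min(k, length(ok))
      near <- ok[order(dist_i[ok])[seq_len(kk)]]
      x[j, i] <- mean(donors[j, near])
    }
  }
  out <- table
  out$intensities <- x
  validate_feature_table(out)
  out
}

#' Generalized logarithm transform
#'
#' `g(x) = ln((x + sqrt(x^2 + lambda)) / 2)`; strictly increasing in x,
#' and equal to `ln(x)` at `lambda = 0`.
#'
#' @param x numeric vector or matrix (strictly positive).
#' @param lambda non-negative transform parameter.
#' @return transformed values, same shape as `x`.
#' @export
glog_transform <- function(x, lambda) {
  log((x + sqrt(x^2 + lambda)) / 2)
}

# Profile negative log-likelihood of the variance-stabilizing glog on QC
# replicates: N*log(RSS/N) minus twice the log-Jacobian sum(log g'(x)),
# g'(x) = 1/sqrt(x^2 + lambda).
glog_objective <- function(lambda, x_qc) {
  g <- glog_transform(x_qc, lambda)
  rss <- sum((g - rowMeans(g))^2)
  n <- length(x_qc)
  n * log(rss / n) + sum(log(x_qc^2 + lambda))
}

#' Optimize the glog parameter on the QC samples
#'
#' Finds the lambda that best stabilizes the technical variance of the QC
#' replicates, by minimizing the profile negative log-likelihood (residual
#' variance of QC replicates in transformed space, with the Jacobian
#' correction) over a log-spaced grid followed by local refinement.
#'
#' @param table a strictly positive [feature_table] (post-imputation).
#' @param meta matching metadata (>= 3 QC samples required).
#' @return the optimized lambda (> 0).
#' @export
glog_fit_lambda <- function(table, meta) {
  check_table_meta(table, meta)
  m <- meta_for(meta, table$sample_ids)
  qc <- which(m$is_qc)
  if (length(qc) < 3) {
    stop("glog optimization needs >= 3 QC samples; pass an explicit lambda",
         call. = FALSE)
  }
  x <- table$intensities[, qc, drop = FALSE]
  if (any(x <= 0)) stop("glog optimization requires a strictly positive table",
                        call. = FALSE)
  scale2 <- stats::median(x)^2
  grid <- scale2 * 10^seq(-8, 4, length.out = 25)
  obj <- vapply(grid, glog_objective, numeric(1), x_qc = x)
  i <- which.min(obj)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(function(ll) glog_objective(exp(ll), x),
                         interval = log(c(lo, hi)))
  exp(opt$minimum)
}

#' Mean centering with training means
#'
#' @param x numeric matrix (features x samples).
#' @param means per-feature means estimated from the training samples; by
#'   default the row means of `x` itself.
#' @return list with `x` (centered) and `means`.
#' @export
mean_center <- function(x, means = rowMeans(x)) {
  list(x = sweep(x, 1L, means, "-"), means = means)
}

#' Average duplicate injections per (patient, condition)
#'
#' Collapses replicates to their arithmetic mean, one column per
#' (patient, condition); QC samples are dropped. Used before univariate
#' analysis.
#'
#' @param table a [feature_table].
#' @param meta matching metadata.
#' @return list with `table` (one column per patient-condition) and
#'   `meta` (sample_id, patient_id, condition).
#' @export
average_duplicates <- function(table, meta) {
  check_table_meta(table, meta)
  m <- meta_for(meta, table$sample_ids)
  study <- which(!m$is_qc)
  key <- paste(m$patient_id[study], m$condition[study], sep = "_")
  groups <- split(study, key)
  x <- vapply(groups, function(i) rowMeans(table$intensities[, i, drop = FALSE]),
              numeric(nrow(table$intensities)))
  if (nrow(table$intensities) == 1L) x <- matrix(x, nrow = 1L)
  ids <- names(groups)
  out <- feature_table(table$feature_ids, table$mz, table$rt, table$mode, x, ids)
  first <- vapply(groups, `[`, numeric(1), 1L)
  list(table = out,
       meta = data.frame(sample_id = ids,
                         patient_id = m$patient_id[first],
                         condition = m$condition[first],
                         stringsAsFactors = FALSE))
}

#' Per-feature fold change between conditions
#'
#' Median over patients of the ratio (mean of duplicates during) /
#' (mean of duplicates before), on the raw (pre-glog) intensity scale.
#'
#' @param table a [feature_table] (raw or normalized scale).
#' @param meta matching metadata.
#' @return named numeric vector of fold changes per feature.
#' @export
compute_fold_changes <- function(table, meta) {
  avg <- average_duplicates(table, meta)
  m <- avg$meta
  pats <- unique(m$patient_id)
  ratios <- vapply(pats, function(p) {
    d <- avg$table$intensities[, m$sample_id[m$patient_id == p & m$condition == "during"]]
    b <- avg$table$intensities[, m$sample_id[m$patient_id == p & m$condition == "before"]]
    d / b
  }, numeric(nrow(avg$table$intensities)))
  if (nrow(avg$table$intensities) == 1L) ratios <- matrix(ratios, nrow = 1L)
  stats::setNames(apply(ratios, 1L, stats::median), table$feature_ids)
}

#' Fit the preprocessing state on training samples
#'
#' All data-driven parameters (retained features, drift curves, PQN
#' reference, glog lambda, centering means, imputation donors) are
#' estimated from the training study samples plus the QC samples only, so
#' that held-out samples can be processed without information leakage.
#'
#' @param table the full [feature_table].
#' @param meta matching metadata.
#' @param train_ids sample ids of the training study samples.
#' @param config a [preprocess_config()].
#' @return an object of class `preprocess_state`.
#' @export
preprocess_fit <- function(table, meta, train_ids = NULL,
                           config = preprocess_config()) {
  check_table_meta(table, meta)
  if (is.null(train_ids)) train_ids <- meta$sample_id[!meta$is_qc]
  qc_ids <- meta$sample_id[meta$is_qc]
  fit_tab <- subset_features(table, samples = c(train_ids, qc_ids))

  filt <- filter_features(fit_tab, meta, config)
  corr <- qc_svr_correct(filt$table, meta, config)
  norm <- pqn_normalize(corr$table, meta)
  imp <- knn_impute(norm$table, k = config$knn_k)
  lambda <- if (identical(config$glog_lambda, "optimize")) {
    glog_fit_lambda(imp, meta)
  } else as.numeric(config$glog_lambda)
  g <- glog_transform(imp$intensities, lambda)
  train_cols <- match(train_ids, imp$sample_ids)
  means <- rowMeans(g[, train_cols, drop = FALSE])

  structure(list(
    feature_ids = filt$table$feature_ids,
    filter_report = filt$report,
    drift = corr$drift,                     # features x injection order
    pqn_reference = norm$reference,
    lambda = lambda,
    center_means = means,
    donors = norm$table$intensities,        # corrected+normalized, zeros kept
    train_ids = train_ids,
    config = config
  ), class = "preprocess_state")
}

#' Apply a fitted preprocessing state to samples
#'
#' Runs the deterministic chain (feature subset, drift correction, PQN,
#' KNN imputation from training donors, glog, centering with training
#' means) on the requested samples using only the fitted state.
#'
#' @param state a `preprocess_state` from [preprocess_fit()].
#' @param table the full [feature_table].
#' @param meta matching metadata.
#' @param ids sample ids to process (default: the state's training ids).
#' @return list with `x` (centered glog matrix, features x samples),
#'   `glog` (uncentered glog matrix) and `raw` (post-imputation raw-scale
#'   matrix).
#' @export
preprocess_apply <- function(state, table, meta, ids = NULL) {
  if (is.null(ids)) ids <- state$train_ids
  tab <- subset_features(table, features = state$feature_ids, samples = ids)
  m <- meta_for(meta, ids)
  x <- tab$intensities / state$drift[, m$injection_order, drop = FALSE]
  x[tab$intensities == 0] <- 0
  tab$intensities <- x
  norm <- pqn_normalize(tab, meta, reference = state$pqn_reference)
  imp <- knn_impute(norm$table, k = state$config$knn_k, donors = state$donors)
  g <- glog_transform(imp$intensities, state$lambda)
  list(x = sweep(g, 1L, state$center_means, "-"),
       glog = g,
       raw = imp$intensities)
}

#' One-shot preprocessing of a full cohort
#'
#' Fits the state on all study samples (plus QCs) and applies it to every
#' sample — the non-cross-validated version of the chain used for
#' cohort-level summaries (fold changes, networks, annotation input).
#'
#' @param table a [feature_table].
#' @param meta matching metadata.
#' @param config a [preprocess_config()].
#' @return list with `state`, `x` (centered glog), `glog`, `raw`, `table`
#'   (imputed raw-scale [feature_table] over all samples) and
#'   `filter_report`.
#' @export
preprocess_full <- function(table, meta, config = preprocess_config()) {
  state <- preprocess_fit(table, meta, train_ids = meta$sample_id[!meta$is_qc],
                          config = config)
  res <- preprocess_apply(state, table, meta, ids = meta$sample_id)
  tab <- subset_features(table, features = state$feature_ids,
                         samples = meta$sample_id)
  tab$intensities <- res$raw
  list(state = state, x = res$x, glog = res$glog, raw = res$raw,
       table = tab, filter_report = state$filter_report)
}
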