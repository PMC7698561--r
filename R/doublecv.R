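#' Double cross-validation plan
#'
#' Patient-stratified double CV: a 5-fold outer loop repeated over 10
#' iterations estimates accuracy; a 4-fold inner loop on the training
#' data tunes latent-variable counts and sparse-method hyperparameters by
#' DQ2. All replicates and both conditions of a patient share a fold, so
#' duplicate correlation never leaks into the accuracy estimate.
#'
#' @param outer_folds outer folds (default 5).
#' @param outer_iterations outer repetitions (default 10).
#' @param inner_folds inner folds (default 4).
#' @param seed RNG seed for the fold draws.
#' @return an object of class `cv_plan`.
#' @export
cv_plan <- function(outer_folds = 5L, outer_iterations = 10L,
                    inner_folds = 4L, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, outer_iterations >= 1)
  structure(list(outer_folds = outer_folds,
                 outer_iterations = outer_iterations,
                 inner_folds = inner_folds, seed = seed),
            class = "cv_plan")
}

#' Patient-level outer fold assignments
#'
#' For each iteration, patients are randomly partitioned into
#' `outer_folds` groups of near-equal size (e.g. 14 patients over 5
#' folds gives sizes 3,3,3,3,2); every patient appears in exactly one
#' test fold per iteration. QC samples are never assigned to folds (they
#' serve preprocessing only).
#'
#' @param meta sample metadata.
#' @param plan a [cv_plan()].
#' @return a list with one named integer vector (patient -> fold) per
#'   iteration.
#' @export
make_folds <- function(meta, plan = cv_plan()) {
  validate_sample_metadata(meta)
  patients <- unique(meta$patient_id[!meta$is_qc])
  if (length(patients) < plan$outer_folds) {
    stop("fewer patients than outer folds", call. = FALSE)
  }
  set.seed(plan$seed)
  lapply(seq_len(plan$outer_iterations), function(it) {
    perm <- sample(patients)
    f <- rep_len(seq_len(plan$outer_folds), length(perm))
    stats::setNames(f[match(patients, perm)], patients)
  })
}

# inner-CV DQ2 over a grid of orthogonal-component counts for OPLS-DA
tune_oplsda <- function(X, y, folds, ortho_grid = 0:5) {
  ortho_grid <- ortho_grid[ortho_grid <= nrow(X) - 2L]
  dq <- vapply(ortho_grid, function(no) {
    yhat <- rep(NA_real_, length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) return(-Inf)
      m <- tryCatch(fit_oplsda(X[tr, , drop = FALSE], y[tr], n_ortho = no),
                    error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      yhat[!tr] <- predict(m, X[!tr, , drop = FALSE])$yhat
    }
    dq2(yhat, y)
  }, numeric(1))
  ortho_grid[order(-dq, ortho_grid)[1L]]
}

# variable selection on a preprocessed training matrix, per method;
# returns selected feature names plus the latent-variable count used for
# the refit model
select_on_training <- function(method, X, y, inner_fold_assign, opts) {
  p <- ncol(X)
  feats <- colnames(X)
  switch(method,
    vip = {
      n_ortho <- tune_oplsda(X, y, inner_fold_assign, opts$ortho_grid)
      A <- min(1L + n_ortho, nrow(X) - 1L, p)
      m <- fit_pls(X, y, A = A)
      v <- vip(m)
      list(selected = feats[v > opts$vip_threshold], A = A,
           tuned = c(n_ortho = n_ortho), stat = v)
    },
    smc = {
      w <- wrt_select_ncomp(X, y, n_perm = opts$wrt_n_perm,
                            alpha = opts$wrt_alpha, seed = opts$seed)
      A <- max(1L, w$n_components)
      m <- fit_pls(X, y, A = A)
      s <- smc(m, X, alpha = opts$smc_alpha, nu = opts$smc_nu)
      list(selected = feats[s$selected], A = A,
           tuned = c(n_comp = A), stat = s$F)
    },
    cars = {
      r <- cars_plsda(X, y, n_runs = opts$cars_runs, n_lv = opts$cars_lv,
                      seed = opts$seed, folds = inner_fold_assign)
      list(selected = feats[r$selected], A = opts$cars_lv,
           tuned = c(best_run = r$best_run), stat = NULL)
    },
    spls = {
      r <- spls_da(X, y, n_lv = opts$spls_lv, seed = opts$seed,
                   folds = inner_fold_assign)
      list(selected = feats[r$selected], A = opts$spls_lv,
           tuned = c(keep = r$keep), stat = NULL)
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Run the double cross-validation comparison
#'
#' Per outer split: preprocessing state is fitted on the training study
#' samples plus all QC samples; the inner CV (patient-grouped) tunes
#' latent-variable counts (and CARS/sPLS subsets) by DQ2 — the WRT route
#' picks its component count by permutation instead; variables are
#' selected on the training data; a PLS-DA model on the selected
#' variables predicts the untouched test fold. Overall accuracy is the
#' mean over all outer splits, and the consensus set per method is the
#' intersection of its selections across splits.
#'
#' @param table the raw [feature_table] (all samples).
#' @param meta sample metadata.
#' @param methods character vector among `"vip"`, `"smc"`, `"cars"`,
#'   `"spls"`.
#' @param plan a [cv_plan()].
#' @param config a [preprocess_config()].
#' @param smc_alpha,smc_nu sMC significance level and residual df
#'   (`NULL` = n - 2).
#' @param vip_threshold VIP selection cutoff (default 1.0).
#' @param wrt_n_perm,wrt_alpha WRT permutation count and level.
#' @param cars_runs,cars_lv CARS runs and latent variables.
#' @param spls_lv sparse PLS-DA latent variables.
#' @return an object of class `cv_result`: `splits` (per-split
#'   data.frame), `accuracy` (named overall mean per method),
#'   `selections` (per method, list of per-split feature-id sets),
#'   `consensus` (per method) and `plan`.
#' @export
run_double_cv <- function(table, meta, methods = c("vip", "smc", "cars", "spls"),
                          plan = cv_plan(), config = preprocess_config(),
                          smc_alpha = 0.01, smc_nu = NULL,
                          vip_threshold = 1.0,
                          wrt_n_perm = 500L, wrt_alpha = 0.05,
                          cars_runs = 50L, cars_lv = 2L, spls_lv = 1L) {
  check_table_meta(table, meta)
  folds_by_iter <- make_folds(meta, plan)
  opts <- list(smc_alpha = smc_alpha, smc_nu = smc_nu,
               vip_threshold = vip_threshold, ortho_grid = 0:5,
               wrt_n_perm = wrt_n_perm, wrt_alpha = wrt_alpha,
               cars_runs = cars_runs, cars_lv = cars_lv, spls_lv = spls_lv,
               seed = plan$seed)
  study_meta <- meta[!meta$is_qc, , drop = FALSE]
  splits <- list()
  selections <- stats::setNames(lapply(methods, function(m) list()), methods)
  split_i <- 0L
  for (it in seq_along(folds_by_iter)) {
    fold_of <- folds_by_iter[[it]]
    for (f in sort(unique(fold_of))) {
      split_i <- split_i + 1L
      test_pat <- names(fold_of)[fold_of == f]
      train_ids <- study_meta$sample_id[!study_meta$patient_id %in% test_pat]
      test_ids <- study_meta$sample_id[study_meta$patient_id %in% test_pat]
      state <- preprocess_fit(table, meta, train_ids, config)
      Xtr <- t(preprocess_apply(state, table, meta, train_ids)$x)
      Xte <- t(preprocess_apply(state, table, meta, test_ids)$x)
      ytr <- code_classes(meta_for(meta, train_ids)$condition)
      yte <- code_classes(meta_for(meta, test_ids)$condition)
      inner_assign <- make_inner_folds(
        ytr, plan$inner_folds, seed = plan$seed + 1000L * split_i,
        groups = meta_for(meta, train_ids)$patient_id)
      for (method in methods) {
        sel <- select_on_training(method, Xtr, ytr, inner_assign, opts)
        failed <- length(sel$selected) < 1L
        if (failed) {
          maj <- if (sum(ytr > 0) >= sum(ytr < 0)) 1 else -1
          acc <- mean(yte == maj)
        } else {
          cols <- match(sel$selected, colnames(Xtr))
          A <- min(sel$A, length(cols), nrow(Xtr) - 1L)
          refit <- fit_pls(Xtr[, cols, drop = FALSE], ytr, A = A)
          pred <- predict(refit, Xte[, cols, drop = FALSE])
          acc <- mean(pred$class == yte)
        }
        selections[[method]][[split_i]] <- sel$selected
        splits[[length(splits) + 1L]] <- data.frame(
          iteration = it, fold = f, method = method, accuracy = acc,
          n_selected = length(sel$selected), failed = failed,
          stringsAsFactors = FALSE)
      }
    }
  }
  splits <- do.call(rbind, splits)
  accuracy <- vapply(methods, function(m)
    mean(splits$accuracy[splits$method == m]), numeric(1))
  consensus <- lapply(selections, consensus_features)
  structure(list(splits = splits, accuracy = accuracy,
                 selections = selections, consensus = consensus,
                 plan = plan),
            class = "cv_result")
}

#' Consensus features across cross-validation selections
#'
#' The intersection of the per-split selected sets: features selected in
#' every outer split. Adding more iterations can only shrink the
#' consensus.
#'
#' @param selections a `cv_result`, or a list of character vectors of
#'   selected feature ids (one per split).
#' @param method when a `cv_result` is given, which method's selections
#'   to intersect (default: all methods, returning a named list).
#' @return a character vector (or named list of vectors) of consensus
#'   feature ids.
#' @export
consensus_features <- function(selections, method = NULL) {
  if (inherits(selections, "cv_result")) {
    if (is.null(method)) return(selections$consensus)
    selections <- selections$selections[[method]]
  }
  if (!length(selections)) stop("no completed splits", call. = FALSE)
  Reduce(intersect, selections)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("double cross-validation: %d folds x %d iterations\n",
              x$plan$outer_folds, x$plan$outer_iterations))
  for (m in names(x$accuracy)) {
    cat(sprintf("  %-6s accuracy %.3f | median selected %d | consensus %d\n",
                m, x$accuracy[[m]],
                as.integer(stats::median(x$splits$n_selected[x$splits$method == m])),
                length(x$consensus[[m]])))
  }
  invisible(x)
}
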