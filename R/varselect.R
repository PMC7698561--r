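# Exact two-sided paired signed-rank p-value by convolution over midranks.
# Doubled ranks keep the support integral when midranks are half-integers;
# the distribution of W+ is symmetric around sum(ranks)/2 because flipping
# all signs is a measure-preserving bijection.
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks
  w2 <- sum(r2[d > 0])
  M2 <- sum(r2)
  counts <- c(1, rep(0, M2))                  # counts[v + 1] = #patterns with W2 = v
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(M2 + 1 - r)])
    counts <- counts + shifted
  }
  hi <- max(w2, M2 - w2)
  lo <- M2 - hi
  p <- (sum(counts[(hi + 1):(M2 + 1)]) + sum(counts[1:(lo + 1)])) / 2^n
  min(p, 1)
}

signed_rank_normal_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2) / 4)
  z <- (abs(w - mu) - 0.5) / sigma   # continuity correction
  min(2 * stats::pnorm(-max(z, 0)), 1)
}

#' Paired Wilcoxon signed-rank test (exact for n <= 25)
#'
#' Two-sided signed-rank test of paired per-patient values (typically
#' duplicate-injection means before vs during treatment). Zero
#' differences are dropped; ties in |difference| use midranks. For
#' n <= 25 pairs the p-value is exact over all 2^n sign assignments
#' (so the minimal attainable p at n = 14 is 2/2^14 = 1.22e-4); above
#' that, a normal approximation with continuity correction is used.
#'
#' @param before,during numeric vectors of paired values, or matrices
#'   (features x patients) for a vectorized per-feature test.
#' @return p-value, or a vector of p-values for matrix input.
#' @export
wilcoxon_paired <- function(before, during) {
  if (is.matrix(before) || is.matrix(during)) {
    before <- as.matrix(before); during <- as.matrix(during)
    stopifnot(all(dim(before) == dim(during)))
    return(apply(during - before, 1L, function(d) {
      if (length(d) <= 25) signed_rank_exact_p(d) else signed_rank_normal_p(d)
    }))
  }
  if (length(before) != length(during)) stop("unpaired vectors", call. = FALSE)
  d <- during - before
  if (length(d) <= 25) signed_rank_exact_p(d) else signed_rank_normal_p(d)
}

#' Paired sign test
#'
#' Exact two-sided binomial sign test on the paired differences (zero
#' differences dropped); available as an alternative to the signed-rank
#' test. Both give the same minimal p when every difference has the same
#' sign.
#'
#' @inheritParams wilcoxon_paired
#' @return p-value(s).
#' @export
paired_sign_test <- function(before, during) {
  one <- function(d) {
    d <- d[d != 0]
    if (!length(d)) {
      warning("all differences are zero; p = 1")
      return(1)
    }
    k <- sum(d > 0)
    min(2 * min(stats::pbinom(k, length(d), 0.5),
                stats::pbinom(length(d) - k, length(d), 0.5)), 1)
  }
  if (is.matrix(before)) return(apply(during - before, 1L, one))
  one(during - before)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Rejects all hypotheses up to the largest i with
#' `p(i) <= i * alpha / m`, and reports the realized (data-driven)
#' p-value cutoff, i.e. the largest rejected p.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param alpha target FDR level (default 0.05).
#' @return list with `rejected` (logical, in input order), `cutoff`
#'   (largest rejected p, `NA` if none) and `n_rejected`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  o <- order(pvalues)
  ps <- pvalues[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  rejected <- rep(FALSE, m)
  cutoff <- NA_real_
  if (length(ok)) {
    istar <- max(ok)
    rejected[o[seq_len(istar)]] <- TRUE
    cutoff <- ps[istar]
  }
  list(rejected = rejected, cutoff = cutoff, n_rejected = sum(rejected))
}

#' Variable influence on projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` with unit-norm
#' weight columns; the mean of squared VIP scores over features is
#' exactly 1, so the conventional selection threshold is VIP > 1.
#'
#' @param model a fitted `pls_model`.
#' @return numeric vector of VIP scores, one per feature.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (sum(model$ssy) <= 0) stop("model explains no response variance", call. = FALSE)
  p <- nrow(model$W)
  w2 <- model$W^2
  sqrt(p * as.numeric(w2 %*% model$ssy) / sum(model$ssy))
}

#' Significance multivariate correlation (sMC)
#'
#' Target projection: the score `t_TP = Xc b / ||b||` summarizes the
#' response-predictive variation of a PLS model; each feature is then
#' F-tested for its regression on `t_TP`:
#' `F_j = SSR_j / (SSE_j / nu)` with `SSR_j = p_TPj^2 (t'Tp t_TP)` and
#' `SSE_j` the residual sum of squares. F values convert to upper-tail
#' p-values of F(1, nu); features with `F > F_crit(alpha)` are selected.
#' The residual degrees of freedom `nu` default to n - 2 but are
#' configurable.
#'
#' @param model a fitted `pls_model` (or `opls_model`).
#' @param X the samples x features matrix the model was fitted on.
#' @param alpha significance level (the study uses 0.01 or 3e-7).
#' @param nu residual degrees of freedom (default `nrow(X) - 2`).
#' @return list with `F`, `p`, `selected` (logical), `F_crit`, `nu`,
#'   `alpha`.
#' @export
smc <- function(model, X, alpha = 0.01, nu = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= 2) stop("sMC needs n > 2", call. = FALSE)
  if (is.null(nu)) nu <- n - 2
  if (inherits(model, "opls_model")) {
    b <- model$pls$b
    x_means <- model$x_means
  } else {
    b <- model$b
    x_means <- model$x_means
  }
  nb <- sqrt(sum(b^2))
  if (nb < 1e-12) stop("regression vector is zero", call. = FALSE)
  Xc <- sweep(X, 2L, x_means, "-")
  t_tp <- as.numeric(Xc %*% b) / nb
  tt <- sum(t_tp^2)
  p_tp <- as.numeric(crossprod(Xc, t_tp)) / tt
  ssr <- p_tp^2 * tt
  sse <- colSums((Xc - outer(t_tp, p_tp))^2)
  F <- ifelse(sse <= 1e-12 * pmax(ssr, 1), Inf, ssr / (sse / nu))
  p <- ifelse(is.infinite(F), 0, stats::pf(F, 1, nu, lower.tail = FALSE))
  F_crit <- stats::qf(1 - alpha, 1, nu)
  list(F = F, p = p, selected = F > F_crit, F_crit = F_crit,
       nu = nu, alpha = alpha)
}

#' Weight randomization test for the number of PLS components
#'
#' For each successive NIPALS component on the deflated matrix, the
#' statistic `s = ||X_a' y||` is compared with its permutation null
#' (y permuted `n_perm` times); the permutation p-value uses the add-one
#' estimator `p = (1 + #{s* >= s}) / (1 + n_perm)`, so it is never below
#' `1/(1 + n_perm)`. Components are kept while p < alpha. No inner
#' cross-validation is needed.
#'
#' @param X samples x features matrix.
#' @param y -1/+1 class codes.
#' @param n_perm number of permutations (default 500).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @param max_comp maximum number of components to test (default 10).
#' @return list with `n_components` (significant count; 0 if even the
#'   first is non-significant), `p_values` (per tested component) and
#'   `n_fitted` (components actually examined).
#' @export
wrt_select_ncomp <- function(X, y, n_perm = 500L, alpha = 0.05, seed = 1L,
                             max_comp = 10L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (length(unique(y)) < 2) stop("degenerate response", call. = FALSE)
  X <- as.matrix(X)
  set.seed(seed)
  Xa <- sweep(X, 2L, colMeans(X), "-")
  yc <- y - mean(y)
  max_comp <- min(max_comp, nrow(X) - 1L, ncol(X))
  pvals <- numeric(0)
  n_sig <- 0L
  for (a in seq_len(max_comp)) {
    v <- crossprod(Xa, yc)
    s <- sqrt(sum(v^2))
    if (s < 1e-12) break
    Yp <- vapply(seq_len(n_perm), function(i) sample(yc), numeric(length(yc)))
    s_perm <- sqrt(colSums(crossprod(Xa, Yp)^2))
    p <- (1 + sum(s_perm >= s)) / (1 + n_perm)
    pvals <- c(pvals, p)
    if (p >= alpha) break
    n_sig <- n_sig + 1L
    w <- v / s
    t <- Xa %*% w
    pv <- crossprod(Xa, t) / sum(t^2)
    Xa <- Xa - t %*% t(pv)
  }
  list(n_components = n_sig, p_values = pvals, n_fitted = length(pvals))
}

# Stratified fold assignment: balanced within each class (or within each
# group when `groups` is given, keeping all samples of a group together).
make_inner_folds <- function(y, n_folds, seed = NULL, groups = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    gu <- sample(unique(groups))
    gf <- rep_len(seq_len(n_folds), length(gu))
    fold <- gf[match(groups, gu)]
  }
  fold
}

# Pooled out-of-fold DQ2 of a PLS model with n_lv components on X[, cols].
inner_cv_dq2 <- function(X, y, n_lv, folds) {
  yhat <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(-Inf)
    A <- min(n_lv, sum(tr) - 1L, ncol(X))
    m <- tryCatch(fit_pls(X[tr, , drop = FALSE], y[tr], A = A),
                  error = function(e) NULL)
    if (is.null(m)) return(-Inf)
    yhat[!tr] <- predict(m, X[!tr, , drop = FALSE])$yhat
  }
  dq2(yhat, y)
}

#' Competitive adaptive reweighted sampling (CARS) for PLS-DA
#'
#' Monte-Carlo shrinkage of the variable set: over `n_runs` runs, a PLS
#' model on the current subset ranks features by |regression
#' coefficient|; an enforced exponentially decreasing schedule (from all
#' features at run 1 to 2/p of them at the last run) keeps the top
#' features, and adaptive reweighted sampling (draws proportional to
#' |b|, with replacement, deduplicated) picks the next subset. Each
#' run's subset is scored by inner-cross-validated DQ2; the best run's
#' subset is returned (ties broken toward the smaller subset).
#'
#' @param X samples x features matrix (p >= 3).
#' @param y -1/+1 class codes.
#' @param n_runs number of runs (default 50).
#' @param n_lv latent variables of the PLS-DA models (the study uses 2).
#' @param inner_folds folds for the inner DQ2 cross-validation
#'   (default 4).
#' @param seed RNG seed.
#' @param folds optional explicit fold assignment vector for the inner
#'   CV (e.g. patient-stratified).
#' @return list with `selected` (column indices), `selected_names`,
#'   `best_run`, `dq2` (per run) and `subsets` (per run).
#' @export
cars_plsda <- function(X, y, n_runs = 50L, n_lv = 2L, inner_folds = 4L,
                       seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 3) stop("CARS needs at least 3 features", call. = FALSE)
  set.seed(seed)
  if (is.null(folds)) folds <- make_inner_folds(y, inner_folds)
  # enforced exponential decrease: ratio 1 at run 1, 2/p at run n_runs
  aa <- (p / 2)^(1 / (n_runs - 1))
  kk <- log(p / 2) / (n_runs - 1)
  subset <- seq_len(p)
  subsets <- vector("list", n_runs)
  dq <- rep(-Inf, n_runs)
  for (i in seq_len(n_runs)) {
    A <- min(n_lv, length(subset), nrow(X) - 1L)
    m <- tryCatch(fit_pls(X[, subset, drop = FALSE], y, A = A),
                  error = function(e) NULL)
    if (is.null(m)) break
    ab <- abs(m$b)
    r_i <- aa * exp(-kk * i)
    min_size <- n_lv + 1L
    n_keep <- min(max(ceiling(r_i * p), min_size), length(subset))
    top <- subset[order(ab, decreasing = TRUE)[seq_len(n_keep)]]
    wts <- ab[match(top, subset)]
    if (sum(wts) <= 0) wts <- rep(1, length(top))
    subset <- sort(unique(sample(top, n_keep, replace = TRUE, prob = wts)))
    # adaptive sampling may deduplicate below the viable model size:
    # refill from the retained top pool in rank order
    if (length(subset) < min_size) {
      refill <- setdiff(top, subset)
      subset <- sort(c(subset, refill[seq_len(min_size - length(subset))]))
    }
    if (length(subset) < min_size) break
    subsets[[i]] <- subset
    dq[i] <- inner_cv_dq2(X[, subset, drop = FALSE], y,
                          min(n_lv, length(subset)), folds)
  }
  done <- which(!vapply(subsets, is.null, logical(1)))
  if (!length(done)) stop("CARS collapsed before completing any run", call. = FALSE)
  sizes <- lengths(subsets[done])
  best <- done[order(-dq[done], sizes)[1L]]
  sel <- subsets[[best]]
  list(selected = sel,
       selected_names = if (!is.null(colnames(X))) colnames(X)[sel] else NULL,
       best_run = best, dq2 = dq[done], subsets = subsets[done])
}

# one sparse-PLS fit: per component, soft-threshold the weight vector so
# exactly `keep` entries survive, then a standard NIPALS step.
spls_fit <- function(X, y, n_lv, keep) {
  X <- as.matrix(X)
  p <- ncol(X)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xa <- sweep(X, 2L, x_means, "-")
  yc <- y - y_mean
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- as.numeric(crossprod(Xa, yc))
    if (sqrt(sum(w^2)) < 1e-12) stop("degenerate response", call. = FALSE)
    k <- min(keep, p)
    delta <- if (k >= p) 0 else sort(abs(w), decreasing = TRUE)[k + 1L]
    w <- sign(w) * pmax(abs(w) - delta, 0)
    w <- w / sqrt(sum(w^2))
    t <- Xa %*% w
    tt <- sum(t^2)
    P[, a] <- crossprod(Xa, t) / tt
    q[a] <- sum(yc * t) / tt
    W[, a] <- w
    Xa <- Xa - t %*% t(P[, a])
  }
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  structure(list(W = W, P = P, q = q, b = b, x_means = x_means,
                 y_mean = y_mean, A = n_lv,
                 support = which(rowSums(abs(W)) > 0)),
            class = c("spls_model"))
}

#' @export
predict.spls_model <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2L, object$x_means, "-")
  yhat <- as.numeric(Xc %*% object$b) + object$y_mean
  list(yhat = yhat, class = ifelse(yhat >= 0, 1, -1))
}

#' Sparse PLS-DA with soft-thresholded weights
#'
#' Per component, the weight vector `X'y` is soft-thresholded with the
#' threshold chosen so that exactly k entries survive; k is tuned over
#' `keep_grid` by inner-cross-validated DQ2 (ties toward smaller k). The
#' selected set is the support of the final weight vectors. With
#' `keep = p` the weights are proportional to the dense PLS weights;
#' with `keep = 1` the single feature maximizing |X'y| is selected.
#'
#' @param X samples x features matrix.
#' @param y -1/+1 class codes.
#' @param n_lv latent variables (the study uses 1).
#' @param keep_grid candidate per-component keep counts (default a
#'   log-ish grid capped at p).
#' @param inner_folds folds for the inner DQ2 tuning (default 4).
#' @param seed RNG seed.
#' @param folds optional explicit inner-CV fold assignment.
#' @return list with `selected` (column indices), `selected_names`,
#'   `keep`, `weights` (feature x component matrix), `dq2` per grid
#'   value and `model`.
#' @export
spls_da <- function(X, y, n_lv = 1L, keep_grid = NULL, inner_folds = 4L,
                    seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(keep_grid)) {
    keep_grid <- unique(pmin(c(1L, 2L, 3L, 5L, 7L, 10L, 15L, 20L, 30L, 50L), p))
  }
  if (!length(keep_grid)) stop("empty keep grid", call. = FALSE)
  set.seed(seed)
  if (is.null(folds)) folds <- make_inner_folds(y, inner_folds)
  dq <- vapply(keep_grid, function(k) {
    yhat <- rep(NA_real_, length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      m <- tryCatch(spls_fit(X[tr, , drop = FALSE], y[tr],
                             min(n_lv, sum(tr) - 1L), k),
                    error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      yhat[!tr] <- predict(m, X[!tr, , drop = FALSE])$yhat
    }
    dq2(yhat, y)
  }, numeric(1))
  best_k <- keep_grid[order(-dq, keep_grid)[1L]]
  model <- spls_fit(X, y, n_lv, best_k)
  list(selected = model$support,
       selected_names = if (!is.null(colnames(X))) colnames(X)[model$support] else NULL,
       keep = best_k, weights = model$W, dq2 = stats::setNames(dq, keep_grid),
       model = model)
}
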