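# brute-force oracle: exact two-sided signed-rank p over all 2^n sign patterns
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  M <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  hi <- max(w_obs, M - w_obs)
  mean(w_all >= hi - 1e-9 | w_all <= (M - hi) + 1e-9)
}

test_that("exact paired Wilcoxon matches full enumeration, including ties", {
  # all 14 differences positive: the Table-1 floor
  expect_equal(wilcoxon_paired(rep(0, 14), rep(1, 14)), 2 / 2^14)
  expect_equal(signif(wilcoxon_paired(rep(0, 14), 1:14), 2), 1.2e-4)
  # perfect symmetry at n = 2
  expect_equal(wilcoxon_paired(c(0, 0), c(1, -1)), 1)
  # random n = 8 vectors, with deliberate ties in |d|
  set.seed(10)
  for (i in 1:10) {
    d <- round(rnorm(8), if (i <= 5) 0 else 2)  # coarse rounding forces ties
    if (all(d == 0)) next
    expect_equal(wilcoxon_paired(rep(0, 8), d), brute_signed_rank_p(d),
                 info = paste("replicate", i))
  }
  # zero differences are dropped; all-zero warns with p = 1
  expect_equal(wilcoxon_paired(c(0, 0, 0), c(0, 1, 2)),
               wilcoxon_paired(c(0, 0), c(1, 2)))
  expect_warning(p <- wilcoxon_paired(rep(1, 5), rep(1, 5)), "zero")
  expect_equal(p, 1)
  # matrix input vectorizes per feature; n > 25 uses the normal path
  B <- matrix(0, 2, 14); D <- rbind(1:14, c(-(1:7), 1:7))
  expect_equal(wilcoxon_paired(B, D), c(2 / 2^14, 1))
  p_big <- wilcoxon_paired(rep(0, 30), rnorm(30, 0.5))
  expect_true(p_big > 0 && p_big <= 1)
})

test_that("the sign test agrees with the signed-rank floor when all signs agree", {
  expect_equal(paired_sign_test(rep(0, 14), rep(1, 14)), 2 / 2^14)
  expect_equal(paired_sign_test(c(0, 0), c(1, -1)), 1)
})

test_that("BH step-up matches the hand-worked example and p.adjust", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(out$n_rejected, 3)
  expect_equal(out$cutoff, 0.03)
  expect_equal(out$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5))$n_rejected, 0)
  expect_true(bh_fdr(0.04, alpha = 0.05)$rejected)

  set.seed(12)
  for (i in 1:10) {
    p <- runif(50)^2
    mine <- bh_fdr(p, 0.05)$rejected
    ref <- p.adjust(p, "BH") <= 0.05
    expect_equal(mine, ref)
  }
  # monotone in alpha: stricter level never adds rejections
  p <- runif(100)
  r1 <- bh_fdr(p, 0.01)$rejected
  r5 <- bh_fdr(p, 0.05)$rejected
  expect_true(all(!r1 | r5))
})

test_that("VIP has unit mean square and flags the informative feature", {
  set.seed(13)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * (4 + i)), 20, 4 + i)
    y <- rep(c(-1, 1), 10)
    X[, 1] <- y + rnorm(20, 0, 0.3)
    m <- fit_pls(X, y, A = 2)
    v <- vip(m)
    expect_equal(mean(v^2), 1, tolerance = 1e-10)
    expect_equal(which.max(v), 1L)
    expect_gte(v[1], sqrt(ncol(X)) / 2)
  }
  # two features contributing equally, one component: both VIP = 1
  y <- rep(c(-1, 1), 10)
  X2 <- cbind(y, y) + matrix(0, 20, 2)
  m2 <- fit_pls(X2 + rnorm(40, 0, 1e-9), y, A = 1)
  expect_equal(vip(m2), c(1, 1), tolerance = 1e-3)
})

test_that("sMC equals the univariate regression-on-target-projection oracle", {
  set.seed(14)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rep(c(-1, 1), 10)
  X[, 2] <- y + rnorm(20, 0, 0.5)
  m <- fit_pls(X, y, A = 2)
  s <- smc(m, X, alpha = 0.01)
  # oracle: per-feature least squares of x_j on t_TP through the origin
  Xc <- sweep(X, 2, colMeans(X))
  t_tp <- as.numeric(Xc %*% m$b) / sqrt(sum(m$b^2))
  for (j in 1:5) {
    fit <- lm(Xc[, j] ~ t_tp - 1)
    ssr <- sum(fitted(fit)^2)
    sse <- sum(resid(fit)^2)
    expect_equal(s$F[j], ssr / (sse / (20 - 2)), tolerance = 1e-8)
    expect_equal(s$p[j], pf(ssr / (sse / 18), 1, 18, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
  # single-column model: the column is exactly proportional to its own
  # target projection, so SSE = 0, F = Inf, p = 0
  X1 <- matrix(y + rnorm(20, 0, 0.2), ncol = 1)
  m1 <- fit_pls(X1, y, A = 1)
  s2 <- smc(m1, X1, alpha = 0.01)
  expect_true(is.infinite(s2$F[1]))
  expect_equal(s2$p[1], 0)

  # the study's printed critical values arise at nu = 62
  expect_equal(round(smc(m, X, alpha = 0.01, nu = 62)$F_crit, 2), 7.06)
  expect_equal(round(smc(m, X, alpha = 3e-7, nu = 62)$F_crit, 2), 32.99)
  # stricter alpha never adds features
  sel_loose <- smc(m, X, alpha = 0.01)$selected
  sel_strict <- smc(m, X, alpha = 3e-7)$selected
  expect_true(all(!sel_strict | sel_loose))
})

test_that("WRT finds a single real component and respects the add-one floor", {
  # one strong latent factor driving y -> exactly 1 significant component
  set.seed(16)
  ones <- 0L
  for (i in 1:20) {
    y <- rep(c(-1, 1), 12)
    X <- outer(y, rnorm(25)) + matrix(rnorm(24 * 25, 0, 0.5), 24, 25)
    w <- wrt_select_ncomp(X, y, n_perm = 199, alpha = 0.05, seed = i)
    ones <- ones + (w$n_components == 1L)
  }
  expect_gte(ones, 17)

  # add-one estimator: p never below 1/(1+n_perm)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rep(c(-1, 1), 10)
  X[, 1] <- y
  w <- wrt_select_ncomp(X, y, n_perm = 199, alpha = 0.05, seed = 1)
  expect_gte(min(w$p_values), 1 / 200)
  expect_error(wrt_select_ncomp(X, y, n_perm = 50), "n_perm")
})

test_that("CARS follows its shrinkage schedule and reaches the exhaustive optimum", {
  set.seed(11)
  n <- 24
  y <- rep(c(-1, 1), each = n / 2)
  X <- cbind(y + rnorm(n, 0, 0.2), y + rnorm(n, 0, 0.3),
             rnorm(n), rnorm(n), rnorm(n))
  colnames(X) <- paste0("V", 1:5)
  folds <- metaboselect:::make_inner_folds(y, 4, seed = 7)
  r <- cars_plsda(X, y, n_runs = 30, n_lv = 2, folds = folds, seed = 1)

  # the enforced schedule runs from the full set down to the model floor
  expect_lte(length(r$subsets[[length(r$subsets)]]), 3L)
  expect_gte(length(r$subsets[[1]]), 3L)
  # reproducible from seed
  r2 <- cars_plsda(X, y, n_runs = 30, n_lv = 2, folds = folds, seed = 1)
  expect_identical(r$selected, r2$selected)

  # exhaustive oracle over all feasible subsets, scored by the same inner CV:
  # CARS keeps the informative pair and matches the optimum's DQ2
  subs <- unlist(lapply(3:5, function(k) combn(5, k, simplify = FALSE)),
                 recursive = FALSE)
  dqs <- vapply(subs, function(s)
    metaboselect:::inner_cv_dq2(X[, s, drop = FALSE], y, 2, folds), numeric(1))
  expect_true(all(c(1, 2) %in% r$selected))
  expect_gte(max(r$dq2), max(dqs) - 0.02)
  expect_error(cars_plsda(X[, 1:2], y), "at least 3")
})

test_that("sparse PLS-DA thresholds exactly and agrees with an independent implementation", {
  to <- toy_xy(n = 24, p = 8, informative = 2, noise = 0.4, seed = 42)
  X <- to$X; y <- to$y
  X[, 5] <- y + rnorm(24, 0, 0.6)

  # keep = p reproduces the dense PLS weights
  dense <- metaboselect:::spls_fit(X, y, n_lv = 1, keep = 8)
  m1 <- fit_pls(X, y, A = 1)
  expect_equal(abs(dense$W[, 1]), abs(m1$W[, 1]), tolerance = 1e-10)

  # keep = 1 selects argmax |X'y|
  one <- metaboselect:::spls_fit(X, y, n_lv = 1, keep = 1)
  v <- abs(crossprod(sweep(X, 2, colMeans(X)), y - mean(y)))
  expect_equal(one$support, which.max(v))

  # cross-check against mixOmics on the same keep count
  skip_if_not_installed("mixOmics")
  ours <- metaboselect:::spls_fit(X, y, n_lv = 1, keep = 3)
  mo <- mixOmics::splsda(X, as.factor(y), ncomp = 1, keepX = 3, scale = FALSE)
  expect_setequal(paste0("V", ours$support),
                  mixOmics::selectVar(mo, comp = 1)$name)

  # tuning picks a sparse k on an easy problem and is seed-reproducible
  folds <- metaboselect:::make_inner_folds(y, 4, seed = 3)
  s1 <- spls_da(X, y, n_lv = 1, folds = folds, seed = 1)
  s2 <- spls_da(X, y, n_lv = 1, folds = folds, seed = 1)
  expect_identical(s1$selected, s2$selected)
  expect_lte(length(s1$selected), 8)
  expect_error(spls_da(X, y, keep_grid = integer(0)), "empty")
})
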