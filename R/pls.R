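#' Code a two-class condition vector as -1/+1
#'
#' `before` is coded -1 and `during` +1.
#'
#' @param condition character vector with values `before`/`during`.
#' @return numeric vector of class codes.
#' @export
code_classes <- function(condition) {
  if (!all(condition %in% c("before", "during"))) {
    stop("condition must be 'before' or 'during'", call. = FALSE)
  }
  ifelse(condition == "during", 1, -1)
}

#' Fit a PLS1 regression / discriminant model (NIPALS)
#'
#' NIPALS with X deflation per component. For a single response the
#' first weight vector is proportional to `X'y`; the regression vector is
#' `b = W (P'W)^{-1} q`, so that `yhat = Xc b + mean(y)` reproduces the
#' training fit. Class membership is the -1/+1 coded condition
#' (PLS-DA).
#'
#' @param X numeric matrix, samples x features. Centered internally with
#'   the column means unless `center = FALSE` (then `X` must already be
#'   centered with training means).
#' @param y numeric response; for discriminant analysis the -1/+1 codes.
#' @param A number of latent variables.
#' @param center center `X` and `y` internally (default `TRUE`).
#' @return an object of class `pls_model` with `W`, `T`, `P`, `q`, `b`,
#'   `x_means`, `y_mean`, `A`, `ssy` (response variance explained per
#'   component).
#' @export
fit_pls <- function(X, y, A = 2L, center = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(unique(y)) < 2) stop("degenerate response: one class only", call. = FALSE)
  x_means <- if (center) colMeans(X) else rep(0, p)
  y_mean <- if (center) mean(y) else 0
  Xc <- sweep(X, 2L, x_means, "-")
  yc <- y - y_mean
  if (A > min(if (center) n - 1L else n, p)) {
    stop(sprintf("A = %d exceeds rank(X) <= %d", A,
                 min(if (center) n - 1L else n, p)), call. = FALSE)
  }
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A); ssy <- numeric(A)
  Xa <- Xc
  for (a in seq_len(A)) {
    w <- crossprod(Xa, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (a == 1L) stop("degenerate response: X'y = 0", call. = FALSE)
      stop(sprintf("A = %d exceeds the effective rank of X (exhausted at %d)",
                   A, a - 1L), call. = FALSE)
    }
    w <- w / nw
    t <- Xa %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xa, t) / tt
    qa <- sum(yc * t) / tt
    Xa <- Xa - t %*% t(pvec)
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
    ssy[a] <- qa^2 * tt
  }
  b <- W %*% solve(crossprod(P, W), q)
  structure(list(W = W, T = Tm, P = P, q = q, b = as.numeric(b),
                 x_means = x_means, y_mean = y_mean, A = A, ssy = ssy,
                 n = n),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix, samples x features, on the raw scale of
#'   the training `X` (training means are subtracted internally).
#' @param ... unused.
#' @return list with `yhat` (real-valued predictions) and `class`
#'   (-1/+1 by sign; a prediction of exactly 0 is assigned +1).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b)) {
    stop(sprintf("newdata has %d features, model expects %d",
                 ncol(newdata), length(object$b)), call. = FALSE)
  }
  Xc <- sweep(newdata, 2L, object$x_means, "-")
  yhat <- as.numeric(Xc %*% object$b) + object$y_mean
  cls <- ifelse(yhat >= 0, 1, -1)
  list(yhat = yhat, class = cls)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal signal correction for a single response: components
#' uncorrelated with y (`w_orth` proportional to `p - (w'p / w'w) w`) are
#' iteratively removed from X, and a one-component PLS model is fitted on
#' the filtered matrix. With `n_ortho = 0` the predictions equal the
#' one-component PLS fit.
#'
#' @param X samples x features matrix.
#' @param y -1/+1 class codes.
#' @param n_ortho number of orthogonal components (>= 0).
#' @return an object of class `opls_model` with the predictive
#'   `pls_model`, orthogonal weights/loadings/scores and `n_ortho`
#'   actually extracted.
#' @export
fit_oplsda <- function(X, y, n_ortho = 0L) {
  X <- as.matrix(X)
  if (n_ortho < 0) stop("n_ortho must be >= 0", call. = FALSE)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_means, "-")
  yc <- y - y_mean
  W_o <- NULL; P_o <- NULL; T_o <- NULL
  Xa <- Xc
  k <- 0L
  while (k < n_ortho) {
    w <- crossprod(Xa, yc); w <- w / sqrt(sum(w^2))
    t <- Xa %*% w
    pvec <- crossprod(Xa, t) / sum(t^2)
    w_orth <- pvec - as.numeric(crossprod(w, pvec)) * w
    nw <- sqrt(sum(w_orth^2))
    if (nw < 1e-12) {
      warning("orthogonal variation exhausted after ", k, " components")
      break
    }
    w_orth <- w_orth / nw
    t_orth <- Xa %*% w_orth
    p_orth <- crossprod(Xa, t_orth) / sum(t_orth^2)
    Xa <- Xa - t_orth %*% t(p_orth)
    W_o <- cbind(W_o, w_orth); P_o <- cbind(P_o, p_orth)
    T_o <- cbind(T_o, t_orth)
    k <- k + 1L
  }
  pred <- fit_pls(Xa, yc, A = 1L, center = FALSE)
  pred$x_means <- rep(0, ncol(X))   # Xa is already centered
  structure(list(pls = pred, W_ortho = W_o, P_ortho = P_o, T_ortho = T_o,
                 n_ortho = k, x_means = x_means, y_mean = y_mean),
            class = "opls_model")
}

#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2L, object$x_means, "-")
  if (object$n_ortho > 0) {
    for (k in seq_len(object$n_ortho)) {
      t_orth <- Xc %*% object$W_ortho[, k]
      Xc <- Xc - t_orth %*% t(object$P_ortho[, k])
    }
  }
  yhat <- as.numeric(Xc %*% object$pls$b) + object$y_mean
  list(yhat = yhat, class = ifelse(yhat >= 0, 1, -1))
}

#' Discriminant Q2
#'
#' Cross-validated explained variance that does not penalize predictions
#' beyond their class label: the residual is zero when `yhat > 1` for a
#' +1 sample or `yhat < -1` for a -1 sample, else `y - yhat`;
#' `DQ2 = 1 - sum(e^2) / sum((y - mean(y))^2)`. Because residuals beyond
#' the label are zeroed, DQ2 is never below the classic Q2.
#'
#' @param yhat real-valued predictions.
#' @param y -1/+1 class codes.
#' @return DQ2 (a real number <= 1).
#' @export
dq2 <- function(yhat, y) {
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1", call. = FALSE)
  if (length(unique(y)) < 2) stop("one-class y: DQ2 undefined", call. = FALSE)
  e <- y - yhat
  e[y == 1 & yhat > 1] <- 0
  e[y == -1 & yhat < -1] <- 0
  1 - sum(e^2) / sum((y - mean(y))^2)
}

#' Classic Q2 (1 - PRESS/TSS)
#'
#' @param yhat real-valued predictions.
#' @param y -1/+1 class codes (or any numeric response).
#' @return Q2.
#' @export
q2 <- function(yhat, y) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}
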