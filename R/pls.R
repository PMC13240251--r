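# Univariate partial least squares regression (PLS1) by the SIMPLS
# algorithm (covariance deflation; no X deflation, so repeated fits inside
# the Monte-Carlo outlier screen stay cheap). Coefficients are accumulated
# per component so one fit serves predictions at every component count.

pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  ncomp <- min(ncomp, n - 1L, p)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  s <- crossprod(Xc, yc)                 # p x 1 covariance vector
  R <- matrix(0, p, ncomp)               # weight vectors
  V <- matrix(0, p, ncomp)               # orthonormal loading basis
  q <- numeric(ncomp)
  a <- 0L
  while (a < ncomp) {
    r <- s
    if (sqrt(sum(r^2)) < 1e-12) break    # no covariance left
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    t <- t / nt; r <- r / nt
    pv <- crossprod(Xc, t)
    a <- a + 1L
    R[, a] <- r
    q[a] <- sum(yc * t)
    v <- pv
    if (a > 1L) {
      Va <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pv)
    }
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    s <- s - v %*% crossprod(v, s)
  }
  ncomp <- a
  if (ncomp == 0L)
    stop("PLSR failed: predictor matrix carries no covariance with y")
  R <- R[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  # cumulative coefficients: B_a = sum_{j<=a} q_j R_j
  B <- R %*% (upper.tri(diag(ncomp), diag = TRUE) * q)
  intercepts <- ybar - as.numeric(crossprod(xbar, B))
  structure(list(coefficients = B, intercepts = intercepts, ncomp = ncomp,
                 xbar = xbar, ybar = ybar),
            class = "pls1")
}

# Predictions at component count `ncomp` (default: all fitted components).
pls1_predict <- function(object, X, ncomp = object$ncomp) {
  ncomp <- min(ncomp, object$ncomp)
  as.numeric(as.matrix(X) %*% object$coefficients[, ncomp] +
               object$intercepts[ncomp])
}

# 10-fold cross-validated RMSE per component count; returns the component
# number minimising CV RMSE (capped at max_components). Fold assignment
# comes from the caller's RNG stream.
pls1_select_ncomp <- function(X, y, max_components = 20, folds = 10) {
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  amax <- min(max_components, ncol(X), n - ceiling(n / folds) - 1L)
  if (amax < 1L) amax <- 1L
  sse <- numeric(amax)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- pls1_fit(X[tr, , drop = FALSE], y[tr], amax)
    for (a in seq_len(amax)) {
      pred <- pls1_predict(fit, X[!tr, , drop = FALSE], min(a, fit$ncomp))
      sse[a] <- sse[a] + sum((y[!tr] - pred)^2)
    }
  }
  rmse_cv <- sqrt(sse / n)
  list(ncomp = which.min(rmse_cv), rmse_cv = rmse_cv)
}
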