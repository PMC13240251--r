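# Independent second-implementer oracles, deliberately written as literal
# straight-line transcriptions so they share no code with the package.

# Vegetation-index formulas, one expression each, from the printed table.
oracle_indices <- function(R450, R550, R670, R720, R800) {
  c(ARVI = (R800 - (2 * R670 - R450)) / (R800 + R670 + 0.5),
    CARI = (R670 - R450) - (R670 - R800),
    CCI2 = (R800 - R670) / (R800 + R670 + 0.1),
    CIgreen = (R800 / R550) - 1,
    CIrededge = (R800 / R720) - 1,
    CNDVI = ((R800 - R670) - (R800 - R450)) /
      ((R800 - R670) + (R800 - R450)),
    CVI = R800^2 / R670,
    CVI2 = R800 / (R720 + 1),
    DVI = R800 - R670,
    EVI = 2.5 * (R800 - R670) / (R800 + 6 * R670 - 7.5 * R450 + 1),
    GNDVI = (R800 - R550) / (R800 + R550),
    MCARI = ((R670 - R450) - (R670 - R800)) / R670,
    NDRE = (R800 - R720) / (R800 + R720),
    NDVI = (R800 - R670) / (R800 + R670),
    NLI = R800 / (R670 + R550),
    PVI = (R800 - R670) - 0.5 * (R800 + R670),
    RVI = R800 / R670,
    SAVI = 2.5 * (R800 - R670) / (R800 + R670 + 0.5),
    TGI = R550 - 0.39 * R670 - 0.61 * R450,
    VARI = (R550 - R670) / (R550 + R670 - R450),
    VIG = (R800 - (2 * R670 + R450)) / (R800 + (2 * R670 + R450)))
}

# Brute-force SPXY trace: recompute every distance from scratch at every
# step with plain double loops.
oracle_spxy_train <- function(X, y, n_train) {
  X <- as.matrix(X)
  n <- nrow(X)
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  d <- dx / max(dx) + if (max(dy) > 0) dy / max(dy) else 0
  best <- c(1L, 2L); bestd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_train) {
    cand <- setdiff(1:n, sel)
    score <- sapply(cand, function(k) min(d[k, sel]))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}
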