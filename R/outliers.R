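# Two-pronged anomaly screening: a K-means / Euclidean-distance rule on the
# SPAD readings and a Monte-Carlo PLSR residual rule on the spectra, with
# paired exclusion of the union so spectra and SPAD stay aligned.

#' SPAD outliers by the K-means distance rule
#'
#' Runs K-means (Euclidean) on the 1-D SPAD values and flags points whose
#' distance to their assigned cluster centre exceeds the mean distance plus
#' twice the standard deviation of the distances, pooled over all points
#' (strict inequality, so a zero-spread distance set flags nothing).
#'
#' @param spad numeric vector of SPAD readings.
#' @param k number of clusters (default 1, the pure centre-distance rule;
#'   with k = 1 the centre is the sample mean).
#' @param ids optional sample ids; defaults to names or indices.
#' @return character vector of flagged ids, with attributes `distances` and
#'   `threshold`.
#' @export
#' @examples
#' spad_outliers_kmeans(c(50, 51, 49, 52, 48, 90))  # flags the 90
spad_outliers_kmeans <- function(spad, k = 1, ids = NULL) {
  n <- length(spad)
  if (is.null(ids)) ids <- if (!is.null(names(spad))) names(spad)
                           else as.character(seq_len(n))
  stopifnot(k >= 1, length(ids) == n)
  if (n < 3 * k) stop("need at least 3*k points (k = ", k, ", n = ", n, ")")
  if (k == 1) {
    centres <- mean(spad)
    assign <- rep(1L, n)
  } else {
    km <- kmeans(spad, centers = k, nstart = 5)
    centres <- as.numeric(km$centers)
    assign <- km$cluster
  }
  d <- abs(spad - centres[assign])
  thr <- mean(d) + 2 * sd(d)
  flagged <- ids[d > thr]
  attr(flagged, "distances") <- setNames(d, ids)
  attr(flagged, "threshold") <- thr
  flagged
}

#' Spectral outliers by Monte-Carlo PLSR residual analysis
#'
#' (1) Selects the PLSR component count minimising 10-fold cross-validated
#' RMSE of SPAD on the spectra, capped at `max_components`; (2) fits the
#' full-data PLSR at that count and records the initial residuals; (3) for
#' each of `n_iter` Monte-Carlo iterations draws `cal_fraction` of the
#' samples without replacement, fits PLSR, and predicts; (4) aggregates a
#' per-sample mean absolute residual and flags samples whose statistic
#' exceeds its mean plus `sd_multiplier` standard deviations.
#'
#' @param spectra samples-x-bands numeric matrix.
#' @param spad response vector (SPAD units).
#' @param max_components PLSR component cap (default 20).
#' @param n_iter Monte-Carlo iterations (default 1000).
#' @param sd_multiplier residual threshold in SDs (default 3).
#' @param cal_fraction calibration fraction per iteration (default 0.8).
#' @param seed integer seed; same seed, same flags.
#' @param ids optional sample ids (default rownames or indices).
#' @param heldout_only if `TRUE`, aggregate residuals only over iterations
#'   in which the sample was held out of the calibration draw; the default
#'   (`FALSE`) predicts all samples at every iteration.
#' @return character vector of flagged ids with attributes `stat`
#'   (per-sample mean |residual|), `threshold`, `ncomp` and
#'   `initial_residuals`.
#' @export
spectral_outliers_mcplsr <- function(spectra, spad, max_components = 20,
                                     n_iter = 1000, sd_multiplier = 3,
                                     cal_fraction = 0.8, seed = 1L,
                                     ids = NULL, heldout_only = FALSE) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  stopifnot(length(spad) == n, n_iter >= 1, cal_fraction > 0, cal_fraction < 1)
  if (n <= max_components)
    max_components <- n - 2L
  if (is.null(ids)) ids <- if (!is.null(rownames(spectra))) rownames(spectra)
                           else as.character(seq_len(n))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sel <- pls1_select_ncomp(spectra, spad, max_components)
  ncomp <- sel$ncomp
  fit0 <- pls1_fit(spectra, spad, ncomp)
  res0 <- spad - pls1_predict(fit0, spectra)
  n_cal <- max(2L, round(cal_fraction * n))
  abs_sum <- numeric(n)
  cnt <- numeric(n)
  for (it in seq_len(n_iter)) {
    cal <- sample.int(n, n_cal)
    fit <- pls1_fit(spectra[cal, , drop = FALSE], spad[cal], ncomp)
    res <- spad - pls1_predict(fit, spectra)
    if (heldout_only) {
      out <- setdiff(seq_len(n), cal)
      abs_sum[out] <- abs_sum[out] + abs(res[out])
      cnt[out] <- cnt[out] + 1
    } else {
      abs_sum <- abs_sum + abs(res)
      cnt <- cnt + 1
    }
  }
  stat <- ifelse(cnt > 0, abs_sum / cnt, 0)
  thr <- mean(stat) + sd_multiplier * sd(stat)
  flagged <- ids[stat > thr]
  attr(flagged, "stat") <- setNames(stat, ids)
  attr(flagged, "threshold") <- thr
  attr(flagged, "ncomp") <- ncomp
  attr(flagged, "initial_residuals") <- setNames(res0, ids)
  flagged
}

#' Paired exclusion of SPAD and spectral outliers
#'
#' Removes the union of the two flagged id lists from the sample set, so
#' spectra linked to anomalous SPAD values and SPAD values linked to
#' anomalous spectra are excluded simultaneously.
#'
#' @param samples `spad_samples` object.
#' @param spad_ids,spectral_ids character id vectors (may be empty).
#' @return list with `samples` (the reduced set) and `report`, an
#'   `spad_outlier_report` recording both lists, the union, before/after
#'   counts and any thresholds passed along.
#' @export
paired_exclude <- function(samples, spad_ids = character(),
                           spectral_ids = character()) {
  stopifnot(inherits(samples, "spad_samples"))
  all_ids <- samples$meta$sample_id
  unknown <- setdiff(c(spad_ids, spectral_ids), all_ids)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  removed <- union(as.character(spad_ids), as.character(spectral_ids))
  keep <- setdiff(all_ids, removed)
  report <- structure(list(
    spad_outlier_ids = as.character(spad_ids),
    spectral_outlier_ids = as.character(spectral_ids),
    removed_ids = removed,
    n_before = length(all_ids), n_after = length(keep),
    thresholds_used = list(
      spad = attr(spad_ids, "threshold"),
      spectral = attr(spectral_ids, "threshold"),
      ncomp = attr(spectral_ids, "ncomp"))),
    class = "spad_outlier_report")
  out <- if (length(removed)) samples[keep] else samples
  out$provenance <- c(out$provenance,
                      sprintf("paired_exclude: removed %d of %d",
                              length(removed), length(all_ids)))
  list(samples = out, report = report)
}

#' @export
print.spad_outlier_report <- function(x, ...) {
  cat(sprintf("outlier screen: %d -> %d samples (%d SPAD, %d spectral, union %d)\n",
              x$n_before, x$n_after, length(x$spad_outlier_ids),
              length(x$spectral_outlier_ids), length(x$removed_ids)))
  invisible(x)
}
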