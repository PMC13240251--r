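# Pearson correlation screening of features (vegetation indices or single
# bands) against SPAD, descriptive |r| magnitude classes, and selection of
# the optimal (chain, index) combination per group.

#' Pearson product-moment correlation
#'
#' The plain product-moment formula,
#' `sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))`. Pairs with a missing (masked) value on either
#' side are dropped listwise.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return correlation coefficient in \[-1, 1\].
#' @export
#' @examples
#' pearson_r(1:4, c(1, 2, 4, 3))  # 0.8
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0) stop("zero variance: correlation undefined")
  sum(dx * dy) / sqrt(vx * vy)
}

#' Classify correlation strength
#'
#' Descriptive magnitude bins: none for `|r| <= 0.3`, weak for
#' `0.3 < |r| <= 0.5`, significant for `0.5 < |r| <= 0.8`, highly
#' significant for `|r| > 0.8` (boundary values fall to the lower class).
#' These are magnitude bins, not hypothesis tests.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return character vector of class labels.
#' @export
#' @examples
#' classify_strength(c(0.3, -0.78, 0.81))
classify_strength <- function(r) {
  a <- abs(r)
  if (any(a > 1 + 1e-12)) stop("|r| > 1")
  cut_lab <- function(v) {
    if (v <= 0.3) "none"
    else if (v <= 0.5) "weak"
    else if (v <= 0.8) "significant"
    else "highly_significant"
  }
  vapply(pmin(a, 1), cut_lab, character(1))
}

#' Per-wavelength correlation of reflectance with SPAD
#'
#' @param samples `spad_samples` object (>= 3 samples).
#' @return data.frame with columns `wavelength` and `r`; bands with zero
#'   variance yield `NA`.
#' @export
bandwise_correlogram <- function(samples) {
  stopifnot(inherits(samples, "spad_samples"), nrow(samples$meta) >= 3)
  y <- samples$meta$spad
  r <- apply(samples$spectra, 2, function(v) {
    if (var(v) == 0 || var(y) == 0) NA_real_ else pearson_r(v, y)
  })
  data.frame(wavelength = samples$wavelengths, r = as.numeric(r))
}

#' Correlate every vegetation index with SPAD
#'
#' @param table `spad_index_table` from [compute_index_table()].
#' @param spad SPAD vector aligned with the table rows.
#' @param group optional group label carried into the result.
#' @return data.frame with one row per index: `group`, `chain`, `feature`,
#'   `r`, `n` (complete pairs used), `n_masked`, `strength_class`.
#' @export
correlate_indices <- function(table, spad, group = NA_character_) {
  stopifnot(inherits(table, "spad_index_table"),
            length(spad) == nrow(table$values))
  rows <- lapply(colnames(table$values), function(nm) {
    v <- table$values[, nm]
    ok <- is.finite(v)
    r <- if (sum(ok) >= 3 && var(v[ok]) > 0) pearson_r(v, spad) else NA_real_
    data.frame(group = group, chain = table$chain, feature = nm, r = r,
               n = sum(ok), n_masked = sum(!ok),
               strength_class = if (is.na(r)) NA_character_
                                else classify_strength(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the optimal (chain, feature) per group
#'
#' Picks, within each group, the feature/chain combination with the largest
#' `|r|`; exact ties are broken by fewer masked samples, then by
#' lexicographic feature name, and flagged in the output.
#'
#' @param results data.frame as produced by [correlate_indices()] (rows
#'   from several chains/groups can be concatenated).
#' @return data.frame with one row per group: the winning `chain`,
#'   `feature`, `r`, plus `tie` (logical).
#' @export
select_optimal <- function(results) {
  stopifnot(all(c("group", "chain", "feature", "r") %in% names(results)))
  if (!nrow(results)) stop("empty results")
  if (!"n_masked" %in% names(results)) results$n_masked <- 0L
  pick <- function(df) {
    df <- df[is.finite(df$r), , drop = FALSE]
    if (!nrow(df)) stop("no finite correlations in group")
    best <- abs(df$r) == max(abs(df$r))
    tie <- sum(best) > 1
    cand <- df[best, , drop = FALSE]
    cand <- cand[order(cand$n_masked, cand$feature), , drop = FALSE]
    out <- cand[1, c("group", "chain", "feature", "r"), drop = FALSE]
    out$tie <- tie
    out
  }
  out <- do.call(rbind, lapply(split(results, results$group), pick))
  rownames(out) <- NULL
  out
}
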