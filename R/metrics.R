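# Model-evaluation statistics: R-squared in its squared-correlation form,
# RMSE with denominator n, RPD with its capability classes, coefficient of
# variation, group summaries, and the relative-SPAD topdressing rule.

#' Coefficient of determination (squared-correlation form)
#'
#' Implemented exactly as the squared Pearson correlation between predicted
#' and actual values -- not as `1 - SSE/SST` -- so it is symmetric in its
#' arguments and invariant to affine transforms of either; for an
#' offset-biased predictor the two definitions differ.
#'
#' @param pred,actual numeric vectors (>= 3 values, nonzero variance).
#' @return value in \[0, 1\].
#' @export
#' @examples
#' r_squared(1:4, c(1, 2, 4, 3))  # 0.64
r_squared <- function(pred, actual) pearson_r(pred, actual)^2

#' Root mean squared error (denominator n)
#'
#' @param pred,actual numeric vectors of equal length.
#' @return nonnegative scalar in the units of the response.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(25/2)
rmse <- function(pred, actual) {
  stopifnot(length(pred) == length(actual), length(pred) >= 1)
  sqrt(mean((pred - actual)^2))
}

#' RPD capability class
#'
#' Bins: `< 1.0` extremely poor, 1.0-1.4 poor, 1.4-1.8 acceptable, 1.8-2.0
#' good, 2.0-2.5 very good, `> 2.5` excellent. The printed bin edges are
#' all strict, so boundary values are assigned to the lower class.
#'
#' @param rpd_value positive RPD value(s).
#' @return character vector of class labels.
#' @export
#' @examples
#' rpd_class(c(0.5, 1.87, 2.5))
rpd_class <- function(rpd_value) {
  lab <- function(v) {
    if (v <= 1.0) "Extremely poor"
    else if (v <= 1.4) "Poor"
    else if (v <= 1.8) "Acceptable"
    else if (v <= 2.0) "Good"
    else if (v <= 2.5) "Very good"
    else "Excellent"
  }
  vapply(rpd_value, lab, character(1))
}

#' Residual prediction deviation (RPD)
#'
#' `RPD = SD / RMSE`, where SD is the sample standard deviation (n - 1) of
#' the actual values.
#'
#' @param actual numeric vector of observed values.
#' @param rmse_value positive RMSE of the predictions.
#' @return list with `value` and `class` (see [rpd_class()]).
#' @export
rpd <- function(actual, rmse_value) {
  stopifnot(rmse_value > 0, length(actual) >= 2)
  v <- sd(actual) / rmse_value
  list(value = v, class = rpd_class(v))
}

metric_set <- function(pred, actual) {
  e <- rmse(pred, actual)
  rp <- rpd(actual, e)
  list(r2 = r_squared(pred, actual), rmse = e, rpd = rp$value,
       rpd_class = rp$class)
}

#' Coefficient of variation in percent
#'
#' @param mean_value,sd_value group mean and standard deviation.
#' @return `100 * sd_value / mean_value`.
#' @export
#' @examples
#' round(cv_percent(54.2, 3.0), 1)  # 5.5
cv_percent <- function(mean_value, sd_value) 100 * sd_value / mean_value

#' Per-group SPAD summary statistics
#'
#' For each (stage, leaf position) group: sample count, maximum, minimum,
#' mean, standard deviation (n - 1) and coefficient of variation in
#' percent. Full precision is returned; the print method rounds to one
#' decimal as such tables are conventionally reported.
#'
#' @param samples `spad_samples` object.
#' @return data.frame of class `spad_group_summary`.
#' @export
group_summary <- function(samples) {
  stopifnot(inherits(samples, "spad_samples"))
  groups <- split_groups(samples)
  rows <- lapply(names(groups), function(k) {
    s <- groups[[k]]$meta$spad
    if (length(s) < 2) stop("group ", k, " has fewer than 2 samples; sd undefined")
    data.frame(stage = groups[[k]]$meta$stage[1],
               leaf_position = groups[[k]]$meta$leaf_position[1],
               n = length(s), max = max(s), min = min(s), mean = mean(s),
               sd = sd(s), cv_percent = cv_percent(mean(s), sd(s)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$stage, STAGE_LEVELS),
                   match(out$leaf_position, LEAF_LEVELS)), ]
  rownames(out) <- NULL
  class(out) <- c("spad_group_summary", "data.frame")
  out
}

#' @export
print.spad_group_summary <- function(x, ...) {
  y <- as.data.frame(x)
  num <- c("max", "min", "mean", "sd", "cv_percent")
  y[num] <- lapply(y[num], round, 1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Relative-SPAD nitrogen topdressing rule
#'
#' The relative SPAD (RS) is the ratio of a test area's SPAD to the SPAD of
#' a well-fertilised (high-nitrogen) control area. `RS < 0.95` indicates
#' nitrogen shortage requiring topdressing; `RS >= 0.95` indicates
#' sufficient nitrogen.
#'
#' @param test_spad SPAD of the test area.
#' @param control_spad SPAD of the high-nitrogen control (> 0).
#' @return list with `ratio` and `decision` (`"topdress"` or
#'   `"sufficient"`).
#' @export
#' @examples
#' relative_spad(50, 55)
relative_spad <- function(test_spad, control_spad) {
  stopifnot(control_spad > 0)
  ratio <- test_spad / control_spad
  list(ratio = ratio,
       decision = if (ratio < 0.95) "topdress" else "sufficient")
}
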