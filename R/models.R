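# SPAD prediction models: deterministic SPXY calibration/validation
# partitioning, single-vegetation-index function regression (linear,
# quadratic, exponential, power) returning classed model objects, and
# multi-index random-forest regression with grid-searched hyperparameters.

#' SPXY calibration/validation partition
#'
#' Deterministic joint-X-Y farthest-point (Kennard-Stone style) selection:
#' pairwise Euclidean distances are computed separately in feature space
#' and response space, each normalised by its maximum, and summed,
#' `d = dX / max(dX) + dY / max(dY)`. The pair with the largest combined
#' distance seeds the training set; points are then added one at a time by
#' maximising the minimum combined distance to the already-selected set,
#' until the training set holds `round((1 - test_fraction) * n)` samples.
#' Ties break toward the lowest index, so the split is fully deterministic
#' and order-invariant for distinct data.
#'
#' @param features numeric matrix (samples x features) or vector.
#' @param target response vector.
#' @param test_fraction held-out fraction, default 0.2 (a 4:1 split).
#' @param ids optional sample ids (default rownames or indices).
#' @return object of class `spad_split`: list with `train_ids`, `test_ids`,
#'   `ratio` and the selection `order`.
#' @export
spxy_split <- function(features, target, test_fraction = 0.2, ids = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  stopifnot(length(target) == n, n >= 5, all(is.finite(X)),
            test_fraction > 0, test_fraction < 1)
  if (is.null(ids)) ids <- if (!is.null(rownames(X))) rownames(X)
                           else as.character(seq_len(n))
  dX <- as.matrix(dist(X))
  dY <- as.matrix(dist(target))
  if (max(dX) == 0) stop("degenerate features: all samples identical")
  d <- dX / max(dX) + if (max(dY) > 0) dY / max(dY) else 0
  n_train <- round((1 - test_fraction) * n)
  if (n_train < 2 || n_train >= n)
    stop("test_fraction leaves no valid train/test sizes")
  # seed with the mutually farthest pair (first hit in column-major order)
  w <- which(d == max(d), arr.ind = TRUE)
  w <- w[w[, 1] < w[, 2], , drop = FALSE]
  sel <- as.integer(w[1, ])
  while (length(sel) < n_train) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(d[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  structure(list(train_ids = ids[sort(sel)], test_ids = ids[-sort(sel)],
                 ratio = 1 - test_fraction, order = ids[sel]),
            class = "spad_split")
}

#' @export
print.spad_split <- function(x, ...) {
  cat(sprintf("SPXY split: %d train / %d test (target train fraction %.2f)\n",
              length(x$train_ids), length(x$test_ids), x$ratio))
  invisible(x)
}

#' Single vegetation-index SPAD regression
#'
#' Fits SPAD on one vegetation index with one of four functional forms:
#' linear and quadratic by ordinary least squares, exponential
#' `y = a * exp(b * x)` and power `y = a * x^b` by nonlinear least squares
#' initialised from the log-linearised OLS fit (errors stay additive on
#' the SPAD scale). In-sample R-squared (squared correlation of fitted vs
#' actual) and RMSE are reported. A power-law fit is refused -- status
#' `"not_fittable"`, no error -- when any index value is nonpositive.
#'
#' @param vi vegetation-index vector.
#' @param spad SPAD response vector (> 0).
#' @param form `"linear"`, `"quadratic"`, `"exponential"` or `"power"`.
#' @return object of class `spad_fit` with the usual `print`, `summary`,
#'   `coef`, `predict`, `residuals` and `plot` methods. `$status` is
#'   `"ok"` or `"not_fittable"`; `$metrics` holds in-sample `r2` and
#'   `rmse`.
#' @export
#' @examples
#' x <- seq(1, 3, length.out = 30)
#' f <- fit_single_index(x, 2 * x + 1, "linear")
#' coef(f)
fit_single_index <- function(vi, spad,
                             form = c("linear", "quadratic",
                                      "exponential", "power")) {
  form <- match.arg(form)
  ok <- is.finite(vi) & is.finite(spad)
  vi <- vi[ok]; spad <- spad[ok]
  if (length(vi) < 5) stop("need at least 5 complete samples")
  df <- data.frame(x = vi, y = spad)
  obj <- list(form = form, status = "ok", data = df, n = nrow(df))
  fit <- switch(form,
    linear = lm(y ~ x, data = df),
    quadratic = lm(y ~ x + I(x^2), data = df),
    exponential = {
      init <- lm(log(y) ~ x, data = df)
      minpack.lm::nlsLM(y ~ a * exp(b * x), data = df,
                        start = list(a = exp(coef(init)[[1]]),
                                     b = coef(init)[[2]]),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    power = {
      if (any(vi <= 0)) {
        obj$status <- "not_fittable"
        obj$reason <- "power form requires strictly positive index values"
        NULL
      } else {
        init <- lm(log(y) ~ log(x), data = df)
        minpack.lm::nlsLM(y ~ a * x^b, data = df,
                          start = list(a = exp(coef(init)[[1]]),
                                       b = coef(init)[[2]]),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    })
  if (obj$status == "ok") {
    obj$fit <- fit
    obj$coefficients <- coef(fit)
    fv <- as.numeric(fitted(fit))
    obj$fitted <- fv
    obj$metrics <- list(
      r2 = if (var(fv) > 0) r_squared(fv, spad) else 0,
      rmse = rmse(fv, spad))
  }
  class(obj) <- "spad_fit"
  obj
}

#' @export
print.spad_fit <- function(x, ...) {
  cat("single-index SPAD regression (", x$form, ")\n", sep = "")
  if (x$status != "ok") {
    cat("status:", x$status, "-", x$reason, "\n")
    return(invisible(x))
  }
  cat("coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("in-sample R2 = %.3f, RMSE = %.3f (n = %d)\n",
              x$metrics$r2, x$metrics$rmse, x$n))
  invisible(x)
}

#' @export
summary.spad_fit <- function(object, ...) {
  print(object)
  if (object$status == "ok") {
    cat("\nunderlying fit:\n")
    print(summary(object$fit))
  }
  invisible(object)
}

#' @export
coef.spad_fit <- function(object, ...) {
  if (object$status != "ok") return(NULL)
  object$coefficients
}

#' @export
predict.spad_fit <- function(object, newdata = NULL, ...) {
  if (object$status != "ok") stop("model was not fittable")
  if (is.null(newdata)) return(object$fitted)
  if (is.numeric(newdata)) newdata <- data.frame(x = newdata)
  as.numeric(predict(object$fit, newdata = newdata))
}

#' @export
residuals.spad_fit <- function(object, ...) {
  if (object$status != "ok") stop("model was not fittable")
  object$data$y - object$fitted
}

#' @export
plot.spad_fit <- function(x, ...) {
  if (x$status != "ok") stop("model was not fittable")
  plot(x$data$x, x$data$y, xlab = "vegetation index", ylab = "SPAD",
       main = paste0("SPAD ~ index (", x$form, ")"), ...)
  ord <- order(x$data$x)
  lines(x$data$x[ord], x$fitted[ord], lwd = 2)
  invisible(x)
}

#' Multi-index random-forest SPAD regression
#'
#' Trains a random forest of regression trees on the vegetation-index
#' table, tuning the ensemble size and the per-split candidate-feature
#' count over a coarse logarithmic grid (`n_trees` in {5, 10, 50, 100,
#' 200, 500, 1000} by default, `mtry` in 1..floor(2/3 * p)) by out-of-bag
#' error on the training partition. The ensemble prediction is the mean of
#' the per-tree predictions. Index columns containing masked values are
#' dropped (and logged) before fitting.
#'
#' @param index_table `spad_index_table` from [compute_index_table()].
#' @param spad SPAD vector aligned with the table rows.
#' @param split `spad_split` from [spxy_split()].
#' @param n_trees_grid candidate ensemble sizes.
#' @param mtry_grid candidate `mtry` values; default 1..floor(2/3 * p).
#' @param seed integer seed; fixed seed gives a reproducible report.
#' @return object of class `spad_rf`: the fitted `randomForest`, the
#'   selected hyperparameters, the OOB search table, train/test metric
#'   sets (R2, RMSE, RPD) and the test RPD capability class.
#' @export
fit_rf <- function(index_table, spad, split,
                   n_trees_grid = c(5, 10, 50, 100, 200, 500, 1000),
                   mtry_grid = NULL, seed = 1L) {
  stopifnot(inherits(index_table, "spad_index_table"),
            inherits(split, "spad_split"),
            length(spad) == nrow(index_table$values))
  X <- index_table$values
  keep <- colSums(!is.finite(X)) == 0
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) stop("all index columns are masked")
  p <- ncol(X)
  if (is.null(mtry_grid)) mtry_grid <- seq_len(max(1L, floor(2 * p / 3)))
  names(spad) <- rownames(X)
  tr <- match(split$train_ids, rownames(X))
  te <- match(split$test_ids, rownames(X))
  if (anyNA(tr) || anyNA(te)) stop("split ids not found in index table")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  search <- expand.grid(n_trees = n_trees_grid, mtry = mtry_grid)
  search$oob_mse <- NA_real_
  for (i in seq_len(nrow(search))) {
    set.seed(seed)
    f <- randomForest::randomForest(X[tr, , drop = FALSE], spad[tr],
                                    ntree = search$n_trees[i],
                                    mtry = search$mtry[i])
    search$oob_mse[i] <- f$mse[length(f$mse)]
  }
  best <- search[which.min(search$oob_mse), ]
  set.seed(seed)
  model <- randomForest::randomForest(X[tr, , drop = FALSE], spad[tr],
                                      ntree = best$n_trees, mtry = best$mtry)
  pred_tr <- as.numeric(predict(model, X[tr, , drop = FALSE]))
  pred_te <- as.numeric(predict(model, X[te, , drop = FALSE]))
  structure(list(model = model, n_trees = best$n_trees, mtry = best$mtry,
                 search = search, dropped_indices = dropped,
                 chain = index_table$chain, split = split, seed = seed,
                 train_metrics = metric_set(pred_tr, spad[tr]),
                 test_metrics = metric_set(pred_te, spad[te]),
                 predictions = list(train = pred_tr, test = pred_te),
                 actual = list(train = spad[tr], test = spad[te])),
            class = "spad_rf")
}

#' @export
print.spad_rf <- function(x, ...) {
  cat(sprintf("random-forest SPAD model (chain '%s'): %d trees, mtry %d\n",
              x$chain, x$n_trees, x$mtry))
  cat(sprintf("train: R2 = %.2f, RMSE = %.2f, RPD = %.2f\n",
              x$train_metrics$r2, x$train_metrics$rmse, x$train_metrics$rpd))
  cat(sprintf("test:  R2 = %.2f, RMSE = %.2f, RPD = %.2f (%s)\n",
              x$test_metrics$r2, x$test_metrics$rmse, x$test_metrics$rpd,
              x$test_metrics$rpd_class))
  invisible(x)
}

#' @export
summary.spad_rf <- function(object, ...) {
  print(object)
  cat("\nOOB search (best rows):\n")
  s <- object$search[order(object$search$oob_mse), ]
  print(head(s, 5), row.names = FALSE)
  invisible(object)
}

#' @export
predict.spad_rf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions$test)
  if (inherits(newdata, "spad_index_table")) newdata <- newdata$values
  as.numeric(predict(object$model, newdata))
}

#' Run the complete SPAD calibration pipeline on a sample set
#'
#' Per (stage, leaf position) group: (1) outlier screening -- K-means rule
#' on SPAD, Monte-Carlo PLSR rule on the raw spectra -- with paired
#' exclusion; (2) summary statistics of the retained SPAD values; (3) each
#' preprocessing chain applied, the 21 vegetation indices computed and
#' correlated with SPAD; (4) selection of the optimal (chain, index) per
#' group and single-index fits with the four functional forms; (5) per
#' chain, an SPXY 4:1 split of the index table and a random-forest fit
#' with train/test metrics.
#'
#' @param samples raw `spad_samples` object.
#' @param chains character vector of chain tags, default the four
#'   canonical chains.
#' @param forms functional forms for the single-index models.
#' @param screen logical: run the outlier screen (default TRUE).
#' @param mc_iter Monte-Carlo iterations for the spectral screen.
#' @param test_fraction SPXY held-out fraction.
#' @param n_trees_grid,mtry_grid forwarded to [fit_rf()].
#' @param seed integer seed controlling every stochastic step.
#' @return object of class `spad_pipeline`: list with `summary`
#'   (per-group SPAD statistics), `outlier_reports`, `correlations` (long
#'   data.frame over group x chain x index), `optimal` (per-group best
#'   combination), `single_fits` (nested list of `spad_fit`), `rf_table`
#'   (per group x chain train/test metrics) and `rf_fits`.
#' @export
run_full_pipeline <- function(samples,
                              chains = c("SG", "SG-SNV", "SG-SNV-DT",
                                         "SG-MSC"),
                              forms = c("linear", "quadratic",
                                        "exponential", "power"),
                              screen = TRUE, mc_iter = 200,
                              test_fraction = 0.2,
                              n_trees_grid = c(5, 10, 50, 100, 200, 500,
                                               1000),
                              mtry_grid = NULL, seed = 1L) {
  stopifnot(inherits(samples, "spad_samples"))
  groups <- split_groups(samples)
  reports <- list(); cors <- list(); fits <- list(); rf_fits <- list()
  rf_rows <- list(); kept <- list()
  for (gk in names(groups)) {
    g <- groups[[gk]]
    if (screen) {
      sp_ids <- spad_outliers_kmeans(g$meta$spad, ids = g$meta$sample_id)
      sx_ids <- spectral_outliers_mcplsr(g$spectra, g$meta$spad,
                                         n_iter = mc_iter, seed = seed,
                                         ids = g$meta$sample_id)
      ex <- paired_exclude(g, sp_ids, sx_ids)
      g <- ex$samples
      reports[[gk]] <- ex$report
    }
    kept[[gk]] <- g
    for (ch in chains) {
      pp <- apply_chain(g, ch)
      it <- compute_index_table(pp)
      cors[[paste(gk, ch)]] <- correlate_indices(it, g$meta$spad, group = gk)
      sp <- spxy_split(it$values[, colSums(!is.finite(it$values)) == 0,
                                 drop = FALSE],
                       g$meta$spad, test_fraction = test_fraction)
      rf <- fit_rf(it, g$meta$spad, sp, n_trees_grid = n_trees_grid,
                   mtry_grid = mtry_grid, seed = seed)
      rf_fits[[paste(gk, ch)]] <- rf
      rf_rows[[paste(gk, ch)]] <- data.frame(
        group = gk, chain = ch,
        train_r2 = rf$train_metrics$r2, train_rmse = rf$train_metrics$rmse,
        train_rpd = rf$train_metrics$rpd,
        test_r2 = rf$test_metrics$r2, test_rmse = rf$test_metrics$rmse,
        test_rpd = rf$test_metrics$rpd,
        test_rpd_class = rf$test_metrics$rpd_class,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cors)
  rownames(correlations) <- NULL
  optimal <- select_optimal(correlations)
  for (i in seq_len(nrow(optimal))) {
    gk <- optimal$group[i]
    g <- kept[[gk]]
    pp <- apply_chain(g, optimal$chain[i])
    vi <- compute_index(pp, optimal$feature[i])
    fits[[gk]] <- lapply(setNames(forms, forms), function(fm)
      fit_single_index(vi, g$meta$spad, fm))
  }
  all_kept <- do.call(rbind, lapply(kept, function(s) s$meta))
  summ <- group_summary(samples[match(all_kept$sample_id,
                                      samples$meta$sample_id)])
  structure(list(summary = summ, outlier_reports = reports,
                 correlations = correlations, optimal = optimal,
                 single_fits = fits,
                 rf_table = {r <- do.call(rbind, rf_rows); rownames(r) <- NULL; r},
                 rf_fits = rf_fits, chains = chains, seed = seed),
            class = "spad_pipeline")
}

#' @export
print.spad_pipeline <- function(x, ...) {
  cat("SPAD calibration pipeline:", nrow(x$summary), "group(s),",
      length(x$chains), "chain(s)\n\nGroup SPAD summary:\n")
  print(x$summary)
  cat("\nOptimal (chain, index) per group:\n")
  print(x$optimal, row.names = FALSE)
  cat("\nRandom-forest results:\n")
  y <- x$rf_table
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write pipeline report tables as CSV
#'
#' Emits the group-summary, correlation, optimal-combination and
#' random-forest tables of a fitted pipeline into a directory.
#'
#' @param x `spad_pipeline` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_pipeline_reports <- function(x, dir) {
  stopifnot(inherits(x, "spad_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, c("group_summary.csv", "correlations.csv",
                            "optimal.csv", "rf_results.csv"))
  write.csv(as.data.frame(x$summary), files[1], row.names = FALSE)
  write.csv(x$correlations, files[2], row.names = FALSE)
  write.csv(x$optimal, files[3], row.names = FALSE)
  write.csv(x$rf_table, files[4], row.names = FALSE)
  invisible(files)
}
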