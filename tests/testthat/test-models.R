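test_that("SPXY split sizes, farthest-pair seeding and determinism", {
  set.seed(60)
  X <- matrix(rnorm(20), 10, 2); y <- rnorm(10)
  sp <- spxy_split(X, y, 0.2)
  expect_length(sp$train_ids, 8)
  expect_length(sp$test_ids, 2)
  expect_setequal(c(sp$train_ids, sp$test_ids), as.character(1:10))
  # the mutually farthest pair under the combined metric starts the train set
  dX <- as.matrix(dist(X)); dY <- as.matrix(dist(y))
  d <- dX / max(dX) + dY / max(dY)
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_true(all(as.character(far) %in% sp$train_ids))
  expect_identical(spxy_split(X, y, 0.2), sp)
  expect_error(spxy_split(matrix(1, 6, 2), rnorm(6), 0.2), "degenerate")
})

test_that("SPXY trace matches the brute-force oracle and ignores row order", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rnorm(n)
    n_train <- round(0.8 * n)
    sp <- spxy_split(X, y, 0.2)
    expect_setequal(sp$train_ids, as.character(oracle_spxy_train(X, y, n_train)))
    # selection order itself matches, not just the final set
    expect_equal(sp$order, as.character(oracle_spxy_train(X, y, n_train)))
    # permutation invariance up to relabeling
    perm <- sample(n)
    ids <- sprintf("id%02d", seq_len(n))
    sp1 <- spxy_split(X, y, 0.2, ids = ids)
    sp2 <- spxy_split(X[perm, ], y[perm], 0.2, ids = ids[perm])
    expect_setequal(sp1$train_ids, sp2$train_ids)
  }
})

test_that("single-index fits recover exact generative forms", {
  x <- seq(0.5, 3, length.out = 40)
  lin <- fit_single_index(x, 2 * x + 1, "linear")
  expect_equal(lin$metrics$r2, 1)
  expect_equal(lin$metrics$rmse, 0, tolerance = 1e-9)
  expect_equal(unname(coef(lin)), c(1, 2), tolerance = 1e-9)
  expect_equal(predict(lin, c(10, 20)), c(21, 41), tolerance = 1e-8)

  set.seed(62)
  yq <- 3 + 0.5 * x - 0.8 * x^2 + rnorm(40, 0, 0.05)
  ql <- fit_single_index(x, yq, "linear")
  qq <- fit_single_index(x, yq, "quadratic")
  expect_gte(qq$metrics$r2, ql$metrics$r2)   # nested models

  ye <- 5 * exp(0.4 * x)
  fe <- fit_single_index(x, ye, "exponential")
  expect_equal(unname(coef(fe)), c(5, 0.4), tolerance = 1e-6)
  yp <- 4 * x^0.7
  fp <- fit_single_index(x, yp, "power")
  expect_equal(unname(coef(fp)), c(4, 0.7), tolerance = 1e-6)
})

test_that("power form reports not-fittable on nonpositive index values", {
  x <- c(-0.3, seq(0.5, 2, length.out = 9))
  f <- fit_single_index(x, 2 * x + 10, "power")
  expect_equal(f$status, "not_fittable")
  expect_null(coef(f))
  expect_error(predict(f, 1), "not fittable")
  expect_output(print(f), "not_fittable")
})

test_that("in-sample R2 equals squared correlation of fitted vs actual", {
  set.seed(63)
  x <- runif(30, 0.2, 2)
  y <- 20 + 8 * x + rnorm(30)
  for (fm in c("linear", "quadratic", "exponential", "power")) {
    f <- fit_single_index(x, y, fm)
    expect_equal(f$metrics$r2, pearson_r(fitted(f$fit), y)^2,
                 tolerance = 1e-9)
  }
})

test_that("random-forest model: ensemble mean, reproducibility, null labels", {
  d <- generate_dataset(one_group_config(n = 80, seed = 64))
  s <- d$samples
  it <- compute_index_table(apply_chain(s, "SG-SNV"))
  sp <- spxy_split(it$values, s$meta$spad, 0.2)
  rf <- fit_rf(it, s$meta$spad, sp, n_trees_grid = c(50, 200),
               mtry_grid = c(3, 7), seed = 7)
  rf2 <- fit_rf(it, s$meta$spad, sp, n_trees_grid = c(50, 200),
                mtry_grid = c(3, 7), seed = 7)
  expect_equal(rf$test_metrics, rf2$test_metrics)    # fixed seed reproduces
  expect_equal(rf$train_metrics$rpd,
               sd(rf$actual$train) / rf$train_metrics$rmse, tolerance = 1e-9)
  expect_equal(rf$test_metrics$rpd_class, rpd_class(rf$test_metrics$rpd))

  # the ensemble prediction is the mean over trees
  pt <- predict(rf$model, it$values[sp$test_ids, ],
                predict.all = TRUE)
  expect_equal(unname(rowMeans(pt$individual)), unname(pt$aggregate),
               tolerance = 1e-9)

  # permuted labels destroy the signal
  set.seed(8)
  yperm <- sample(s$meta$spad)
  rfp <- fit_rf(it, yperm, sp, n_trees_grid = 100, mtry_grid = 7, seed = 7)
  expect_lt(rfp$test_metrics$r2, 0.15)
})

test_that("growing the ensemble does not degrade training fit", {
  d <- generate_dataset(one_group_config(n = 60, seed = 66))
  it <- compute_index_table(apply_chain(d$samples, "SG-SNV"))
  sp <- spxy_split(it$values, d$samples$meta$spad, 0.2)
  r2_at <- function(nt) fit_rf(it, d$samples$meta$spad, sp,
                               n_trees_grid = nt, mtry_grid = 7,
                               seed = 5)$train_metrics$r2
  expect_gte(r2_at(500), r2_at(5) - 0.02)
})

test_that("masked index columns are dropped and logged before RF", {
  d <- generate_dataset(one_group_config(n = 40, seed = 65))
  it <- compute_index_table(d$samples)
  it$values[5, "RVI"] <- NA
  sp <- spxy_split(it$values[, -match("RVI", colnames(it$values))],
                   d$samples$meta$spad, 0.2)
  rf <- fit_rf(it, d$samples$meta$spad, sp, n_trees_grid = 50,
               mtry_grid = 3, seed = 1)
  expect_equal(rf$dropped_indices, "RVI")
})
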