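test_that("Pearson correlation matches hand computation and affine laws", {
  expect_equal(pearson_r(1:4, c(1, 2, 4, 3)), 0.8)
  x <- c(2, 5, 1, 9, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 7), -1)
  expect_equal(pearson_r(x, 3 * x + 2), 1)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "3 complete pairs")
  # masked pairs are dropped listwise
  expect_equal(pearson_r(c(1, 2, 3, 4, NA), c(1, 2, 4, 3, 10)), 0.8)
})

test_that("strength classes honour the printed boundaries", {
  expect_equal(classify_strength(0.3), "none")
  expect_equal(classify_strength(-0.78), "significant")
  expect_equal(classify_strength(0.81), "highly_significant")
  expect_equal(classify_strength(c(0, -0.3, 0.31, 0.5, -0.51, 0.8)),
               c("none", "none", "weak", "weak", "significant",
                 "significant"))
  expect_error(classify_strength(1.2), "\\|r\\| > 1")
})

test_that("bandwise correlogram locates the red-edge minimum", {
  s <- generate_dataset(one_group_config(n = 300, seed = 42))$samples
  bc <- bandwise_correlogram(s)
  expect_equal(nrow(bc), 751)
  wmin <- bc$wavelength[which.min(bc$r)]
  expect_gte(wmin, 680); expect_lte(wmin, 740)
  # noise-free construction: negative wherever the kernel absorbs
  s0 <- generate_dataset(one_group_config(n = 30, seed = 9,
                                          scatter_gain_sd = 0,
                                          scatter_offset_sd = 0,
                                          baseline_slope_sd = 0,
                                          baseline_curv_sd = 0,
                                          noise_sd = 0,
                                          gain_spad_coupling = 0,
                                          carotenoid_sd = 0))$samples
  bc0 <- bandwise_correlogram(s0)
  absorbing <- spadspec:::absorb_kernel(s0$wavelengths) > 1e-6
  expect_true(all(bc0$r[absorbing] < 0))
  # constant band is masked
  expect_true(all(is.na(bc0$r[!absorbing])))
})

test_that("optimal selection takes max |r| with documented tie-breaks", {
  res <- data.frame(group = "g", chain = c("A", "B", "C"),
                    feature = c("F1", "F2", "F3"),
                    r = c(0.5, -0.78, 0.76), n = 10, n_masked = 0)
  top <- select_optimal(res)
  expect_equal(top$feature, "F2")
  expect_equal(top$r, -0.78)
  expect_false(top$tie)

  tie <- data.frame(group = "g", chain = "A", feature = c("B2", "A1"),
                    r = c(0.9, -0.9), n = 10, n_masked = c(0, 0))
  expect_equal(select_optimal(tie)$feature, "A1")   # lexicographic
  expect_true(select_optimal(tie)$tie)
  tie$n_masked <- c(0, 2)
  expect_equal(select_optimal(tie)$feature, "B2")   # fewer masked wins

  single <- res[2, ]
  expect_equal(select_optimal(single)$feature, "F2")
  # order invariance
  expect_equal(select_optimal(res[c(3, 1, 2), ]), select_optimal(res))
})

test_that("index correlation table carries group, n and classes", {
  s <- generate_dataset(one_group_config(n = 40, seed = 13))$samples
  it <- compute_index_table(apply_chain(s, "SG-SNV"))
  co <- correlate_indices(it, s$meta$spad, group = "V12/apical")
  expect_equal(nrow(co), 21)
  expect_true(all(abs(co$r) <= 1, na.rm = TRUE))
  expect_equal(co$strength_class,
               unname(classify_strength(co$r)))
  expect_true(all(co$n + co$n_masked == 40))
})
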