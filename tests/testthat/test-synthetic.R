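test_that("spectrum model honours the absorption-kernel support", {
  wl <- 325:1075
  r1 <- generate_spectrum(0.5, wl)
  r2 <- generate_spectrum(0.9, wl)
  # more chlorophyll -> darker red band; NIR untouched (kernel support)
  expect_lt(band(r2, 670, wl), band(r1, 670, wl))
  expect_identical(band(r1, 900, wl), band(r2, 900, wl))
  expect_identical(band(r1, 1050, wl), band(r2, 1050, wl))
  expect_true(all(r1 > 0 & r1 < 1))
  expect_error(generate_spectrum(-1, wl), "latent_chlorophyll")
  expect_error(generate_spectrum(0.5, c(400, 402, 404)), "1 nm")
})

test_that("gain and offset act as pure multiplicative/additive artifacts", {
  wl <- 325:1075
  base <- generate_spectrum(0.7, wl)
  scaled <- generate_spectrum(0.7, wl, gain = 1.1, offset = 0.02)
  expect_equal(unname(scaled), unname(base * 1.1 + 0.02), tolerance = 1e-12)
  # polynomial baseline: quadratic coefficients reproduce exactly
  u <- (wl - 700) / 375
  curved <- generate_spectrum(0.7, wl, offset = c(0.01, 0.005, 0.004))
  expect_equal(unname(curved - base),
               0.01 + 0.005 * u + 0.004 * u^2, tolerance = 1e-12)
})

test_that("generated datasets are deterministic and match the group moments", {
  cfg <- one_group_config(n = 225, mean = 54.2, sd = 3.0, stage = "V6",
                          seed = 4)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$truth, d2$truth)
  # sample CV close to the configured 100*3.0/54.2 = 5.5%
  gs <- group_summary(d1$samples)
  expect_lt(abs(gs$cv_percent - 5.5), 1.5)
  expect_true(all(d1$samples$meta$spad > 0 & d1$samples$meta$spad < 100))
})

test_that("SPAD couples negatively to visible bands, non-negatively to NIR", {
  cfg <- one_group_config(n = 300, seed = 42)
  s <- generate_dataset(cfg)$samples
  expect_lt(pearson_r(band(s, 670), s$meta$spad), 0)
  expect_gte(pearson_r(band(s, 800), s$meta$spad), 0)
})

test_that("noise-free coupling is perfectly monotone across 450-700 nm", {
  cfg <- one_group_config(n = 40, seed = 8, scatter_gain_sd = 0,
                          scatter_offset_sd = 0, baseline_slope_sd = 0,
                          baseline_curv_sd = 0, noise_sd = 0,
                          gain_spad_coupling = 0, carotenoid_sd = 0)
  s <- generate_dataset(cfg)$samples
  vis <- s$spectra[, s$wavelengths >= 450 & s$wavelengths <= 700]
  expect_equal(cor(rowMeans(vis), s$meta$spad, method = "spearman"), -1)
})

test_that("planted outliers are flagged in the truth before corruption", {
  cfg <- one_group_config(n = 100, seed = 5, outlier_fraction = 0.1,
                          outlier_type = "spad")
  d <- generate_dataset(cfg)
  expect_equal(sum(d$truth$is_planted_outlier), 10)
  # SPAD outliers keep their spectrum: reflectance consistent with the
  # clean latent chlorophyll, recorded SPAD far from it
  out <- which(d$truth$is_planted_outlier)
  clean_spad <- log(d$truth$latent_chlorophyll[out] / 0.12) / 0.035
  expect_true(all(abs(d$samples$meta$spad[out] - clean_spad) >
                    5 * 4.3 - 1e-6))
  cfg0 <- one_group_config(n = 50, seed = 5, outlier_fraction = 0)
  expect_equal(sum(generate_dataset(cfg0)$truth$is_planted_outlier), 0)
  expect_error(generator_config(groups = default_groups(),
                                outlier_fraction = 0.5), "outlier_fraction")
})

test_that("two renderings of one leaf agree after SNV up to noise", {
  wl <- 325:1075
  a <- generate_spectrum(0.8, wl, gain = 0.9, offset = 0.03)
  b <- generate_spectrum(0.8, wl, gain = 1.2, offset = -0.01)
  expect_gt(max(abs(a - b)), 0.01)            # scatter visibly differs
  expect_equal(snv(a), snv(b), tolerance = 1e-9)  # SNV removes it exactly
})
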