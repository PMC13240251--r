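test_that("Savitzky-Golay reproduces polynomials up to its order", {
  wl <- 400:500
  quad <- 0.2 + 0.001 * (wl - 450) + 2e-5 * (wl - 450)^2
  expect_equal(sg_smooth(quad, 15, 2), quad, tolerance = 1e-9)
  expect_equal(sg_smooth(rep(0.3, 101), 15, 2), rep(0.3, 101))
  expect_error(sg_smooth(quad, 14, 2))
  expect_error(sg_smooth(quad, 201, 2), "window")
})

test_that("Savitzky-Golay attenuates noise on a smooth signal", {
  set.seed(31)
  wl <- seq_len(401)
  truth <- 0.4 + 0.1 * sin(wl / 30)
  noisy <- truth + rnorm(401, 0, 0.01)
  sm <- sg_smooth(noisy, 15, 2)
  expect_lt(var(sm - truth), var(noisy - truth))
})

test_that("SNV standardises each spectrum with the n-1 denominator", {
  expect_equal(snv(c(0.1, 0.2, 0.3)), c(-1, 0, 1))
  set.seed(2); x <- runif(50)
  expect_equal(mean(snv(x)), 0, tolerance = 1e-12)
  expect_equal(sd(snv(x)), 1, tolerance = 1e-12)
  expect_equal(snv(3 * x + 2), snv(x), tolerance = 1e-12)  # affine invariance
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-12)     # idempotence
  expect_error(snv(rep(0.5, 10)), "constant")
})

test_that("detrending annihilates polynomials and is orthogonal to them", {
  wl <- 325:1075
  poly2 <- 0.3 + 1e-4 * (wl - 700) + 1e-7 * (wl - 700)^2
  expect_equal(detrend(poly2, wl, 2), rep(0, length(wl)), tolerance = 1e-9)
  set.seed(3); x <- runif(length(wl), 0.1, 0.5)
  dt <- detrend(x, wl, 2)
  B <- cbind(1, poly(wl, 2))
  expect_true(all(abs(crossprod(B, dt)) < 1e-9))
  # adding a removable trend does not change the residual spectrum
  expect_equal(detrend(x + 0.05 + 2e-4 * wl, wl, 2), dt, tolerance = 1e-9)
})

test_that("MSC inverts gain/offset corruption against the reference", {
  wl <- 325:1075
  ref <- generate_spectrum(0.7, wl)
  x <- 0.5 + 2 * ref
  expect_equal(unname(msc(x, ref)), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(msc(ref, ref)), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  # two scatter-corrupted renderings collapse onto each other
  a <- generate_spectrum(0.8, wl, gain = 0.8, offset = 0.04)
  b <- generate_spectrum(0.8, wl, gain = 1.3, offset = -0.02)
  pre <- sqrt(sum((a - b)^2))
  m <- msc(rbind(a, b))
  post <- sqrt(sum((m[1, ] - m[2, ])^2))
  expect_lt(post, 0.05 * pre)
  expect_error(msc(matrix(0.3, 1, 10), "mean"), "at least 2")
})

test_that("chains validate step order and compose as tagged pipelines", {
  expect_error(preprocessing_chain(c("SNV", "SG")), "first")
  expect_error(preprocessing_chain("SG-XYZ"), "unknown")
  ch <- preprocessing_chain("SG-SNV-DT")
  expect_equal(ch$steps, c("SG", "SNV", "DT"))

  s <- generate_dataset(one_group_config(n = 12, seed = 6))$samples
  pp <- apply_chain(s, ch)
  expect_equal(pp$chain, "SG-SNV-DT")
  expect_equal(dim(pp$spectra), dim(s$spectra))
  # the detrend residual property survives the whole chain
  expect_true(all(abs(rowMeans(pp$spectra)) < 1e-9))

  # MSC reference is recorded and reusable on held-out data
  msc_fit <- apply_chain(s[1:8], "SG-MSC")
  ref <- attr(msc_fit, "msc_reference")
  expect_length(ref, length(s$wavelengths))
  frozen <- apply_chain(s[9:12], preprocessing_chain("SG-MSC",
                                                     msc_reference = ref))
  refit <- apply_chain(s[9:12], "SG-MSC")
  expect_false(isTRUE(all.equal(frozen$spectra, refit$spectra)))
})

test_that("a smooth spectrum passes through an SG-only chain unchanged", {
  wl <- 325:1075
  s <- tiny_samples(1, wl)
  s$spectra[1, ] <- 0.2 + 1e-4 * (wl - 700)   # linear, SG-reproducible
  out <- apply_chain(s, "SG")
  expect_equal(out$spectra, s$spectra, tolerance = 1e-9)
})
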