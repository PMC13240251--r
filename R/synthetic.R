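# Synthetic leaf-spectrum generator.
#
# Parametric template model: a smooth sigmoidal NIR-plateau baseline minus a
# chlorophyll-scaled absorption kernel concentrated in the visible (blue and
# red Gaussian lobes, a weaker green shoulder) that is ramped to exactly zero
# across the 700-750 nm red edge, so NIR reflectance carries no direct
# chlorophyll signal. Scatter enters as per-leaf multiplicative gain and
# additive offset, plus white measurement noise -- exactly the artifact
# classes SNV/MSC/detrend are designed to remove.

base_template <- function(wl) 0.10 + 0.40 / (1 + exp(-(wl - 705) / 28))

absorb_kernel <- function(wl, carotenoid = 1) {
  g <- function(mu, sig) exp(-0.5 * ((wl - mu) / sig)^2)
  # blue (carotenoid-overlapped) lobe, weak green shoulder, and a red lobe
  # peaking at the red edge: the kernel is the linearised sensitivity of
  # reflectance to chlorophyll over the working range, and in mature green
  # leaves the 660-680 nm absorption core is optically saturated, so the
  # usable sensitivity sits on the red-edge flank. `carotenoid` scales the
  # accessory-pigment absorption (400-550 nm) to emulate leaf-to-leaf
  # pigment-ratio variation.
  raw <- carotenoid * (0.30 * g(450, 35) + 0.18 * g(550, 55)) +
    1.00 * g(700, 30)
  ramp <- ifelse(wl <= 700, 1,
                 ifelse(wl >= 750, 0, 0.5 * (1 + cos(pi * (wl - 700) / 50))))
  0.12 * raw * ramp
}

# Fixed monotone SPAD -> latent chlorophyll link. Exponential rather than
# affine because SPAD meters saturate at high chlorophyll, so chlorophyll
# grows convexly with the SPAD reading; only monotonicity matters to the
# pipeline.
chl_from_spad <- function(spad) 0.12 * exp(0.035 * spad)

#' Render one synthetic leaf reflectance spectrum
#'
#' Reflectance is `gain * (base(lambda) - chl * absorb(lambda)) + offset +
#' noise`, clipped to (0, 1), where `base` is a smooth NIR-plateau template
#' and `absorb` a fixed nonnegative absorption kernel supported in
#' 450-700 nm with a red-edge ramp to zero over 700-750 nm. Higher
#' chlorophyll therefore lowers visible reflectance (negative SPAD
#' correlation below 700 nm) and leaves the NIR plateau untouched.
#'
#' @param latent_chlorophyll positive scalar driving visible absorption.
#' @param wavelengths strictly increasing integer nm grid at 1 nm
#'   (default 325:1075).
#' @param gain per-leaf multiplicative scatter artifact.
#' @param offset additive baseline: up to three polynomial coefficients
#'   (constant, slope, curvature) in the scaled wavelength
#'   `u = (lambda - 700) / 375`; a scalar gives a flat offset.
#' @param noise_sd standard deviation of additive white noise (reflectance
#'   units); drawn from the current RNG stream when > 0.
#' @param carotenoid relative blue-lobe (carotenoid) absorption strength;
#'   1 keeps the fixed kernel.
#' @return numeric reflectance vector named by wavelength.
#' @export
#' @examples
#' r <- generate_spectrum(0.7)
#' plot(325:1075, r, type = "l", xlab = "wavelength (nm)",
#'      ylab = "reflectance")
generate_spectrum <- function(latent_chlorophyll, wavelengths = 325:1075,
                              gain = 1, offset = 0, noise_sd = 0,
                              carotenoid = 1) {
  stopifnot(length(latent_chlorophyll) == 1, latent_chlorophyll > 0,
            length(offset) >= 1, length(offset) <= 3)
  check_grid(wavelengths)
  u <- (wavelengths - 700) / 375
  baseline <- offset[1] + (if (length(offset) > 1) offset[2] * u else 0) +
    (if (length(offset) > 2) offset[3] * u^2 else 0)
  r <- gain * (base_template(wavelengths) -
                 latent_chlorophyll *
                   absorb_kernel(wavelengths, carotenoid)) + baseline
  if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  names(r) <- wavelengths
  r
}

# Per-group SPAD distribution parameters the generator targets by default:
# nine (stage, leaf position) groups with means, SDs and sample counts
# typical of replicated maize field campaigns (CV kept below 10%).
#' Default per-group design for the synthetic generator
#'
#' @return data.frame with columns `stage`, `leaf_position`, `n`,
#'   `spad_mean`, `spad_sd`.
#' @export
default_groups <- function() {
  data.frame(
    stage = c("V6", "V8", "V12", "R1", "R1", "R1", "R2", "R2", "R2"),
    leaf_position = c("apical", "apical", "apical",
                      "upper_ear", "ear", "lower_ear",
                      "upper_ear", "ear", "lower_ear"),
    n = c(225L, 219L, 228L, 227L, 228L, 228L, 224L, 228L, 229L),
    spad_mean = c(54.2, 53.5, 50.6, 55.9, 55.8, 50.6, 61.7, 60.0, 61.2),
    spad_sd = c(3.0, 3.4, 4.3, 5.3, 5.3, 4.3, 5.8, 5.2, 5.0),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic dataset generator
#'
#' @param groups data.frame as [default_groups()]: one row per
#'   (stage, leaf_position) group with `n`, `spad_mean`, `spad_sd`.
#' @param scatter_gain_sd SD of the per-leaf multiplicative gain around 1
#'   (dimensionless).
#' @param scatter_offset_sd SD of the per-leaf additive baseline offset
#'   (reflectance units).
#' @param baseline_slope_sd,baseline_curv_sd SDs of the per-leaf baseline
#'   tilt and curvature coefficients over the scaled wavelength
#'   `u = (lambda - 700) / 375` (reflectance units); the smooth drift the
#'   detrend step is designed to remove.
#' @param noise_sd SD of per-band white noise (reflectance units).
#' @param gain_spad_coupling slope tying gain weakly and positively to the
#'   group-standardised SPAD, emulating the mesophyll-driven positive
#'   NIR-SPAD correlation seen in real leaves.
#' @param carotenoid_sd log-scale SD of the per-leaf carotenoid (blue-lobe)
#'   absorption factor, emulating pigment-ratio variation between leaves.
#' @param outlier_fraction fraction of planted outliers per group, in
#'   \[0, 0.2\].
#' @param outlier_type `"mixed"` (SPAD and spectral kinds at random);
#'   `"spad"` (shifted recorded SPAD, spectrum untouched); `"spectral"`
#'   (mispaired spectrum: re-rendered from a displaced latent-chlorophyll
#'   state, as when SPAD and spectrum are read from different leaves or
#'   spots -- on-manifold, so it does not degrade the calibration, but
#'   confidently mispredicted); `"spike"` (band-localised artifact in
#'   the red/red-edge region); or `"gain"` (gross gain doubling; a PLSR
#'   screen trained on scatter-rich spectra is nearly scale-invariant, so
#'   such anomalies are largely invisible to the residual rule -- and
#'   nearly harmless to SPAD calibration).
#' @param varieties,nitrogen factor levels cycled over samples.
#' @param wavelengths nm grid.
#' @param seed integer RNG seed; identical configs generate byte-identical
#'   datasets.
#' @return object of class `spad_generator_config`.
#' @export
generator_config <- function(groups = default_groups(),
                             scatter_gain_sd = 0.03,
                             scatter_offset_sd = 0.012,
                             baseline_slope_sd = 0.01,
                             baseline_curv_sd = 0.008,
                             noise_sd = 0.003,
                             gain_spad_coupling = 0.02,
                             carotenoid_sd = 0.3,
                             outlier_fraction = 0,
                             outlier_type = c("mixed", "spad", "spectral",
                                              "spike", "gain"),
                             varieties = c("ZD958", "YK918"),
                             nitrogen = c("N0", "N2", "N4"),
                             wavelengths = 325:1075,
                             seed = 1L) {
  outlier_type <- match.arg(outlier_type)
  stopifnot(is.data.frame(groups), nrow(groups) >= 1,
            all(c("stage", "leaf_position", "n", "spad_mean", "spad_sd") %in%
                  names(groups)),
            all(groups$spad_sd > 0), all(groups$n >= 1),
            outlier_fraction >= 0, outlier_fraction <= 0.2,
            scatter_gain_sd >= 0, scatter_offset_sd >= 0, noise_sd >= 0,
            carotenoid_sd >= 0, baseline_slope_sd >= 0, baseline_curv_sd >= 0)
  check_grid(wavelengths)
  cv <- 100 * groups$spad_sd / groups$spad_mean
  if (any(cv >= 10))
    warning("group CV at or above 10%: ",
            paste(sprintf("%s/%s (%.1f%%)", groups$stage,
                          groups$leaf_position, cv)[cv >= 10], collapse = ", "))
  structure(list(groups = groups, scatter_gain_sd = scatter_gain_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 baseline_curv_sd = baseline_curv_sd, noise_sd = noise_sd,
                 gain_spad_coupling = gain_spad_coupling,
                 carotenoid_sd = carotenoid_sd,
                 outlier_fraction = outlier_fraction,
                 outlier_type = outlier_type, varieties = varieties,
                 nitrogen = nitrogen, wavelengths = wavelengths,
                 seed = as.integer(seed)),
            class = "spad_generator_config")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Generate a paired synthetic (spectra, SPAD, metadata) dataset
#'
#' SPAD is drawn per group from a Normal truncated to (0, 100); latent
#' chlorophyll is a fixed affine increasing function of SPAD; spectra are
#' rendered by [generate_spectrum()] with per-leaf gain/offset scatter and
#' white noise. Planted outliers are flagged in the returned truth before
#' corruption: SPAD outliers get a 5-8 group-SD shift of the recorded SPAD
#' (spectrum untouched), spectral outliers a gross gain doubling or a
#' band-localised spike (SPAD untouched).
#'
#' @param config `spad_generator_config` from [generator_config()].
#' @return list of class `spad_synthetic` with elements `samples`
#'   (`spad_samples`) and `truth` (data.frame: `sample_id`,
#'   `latent_chlorophyll`, `gain`, `offset`, `is_planted_outlier`,
#'   `outlier_kind`), plus the `config` used.
#' @export
#' @examples
#' cfg <- generator_config(groups = default_groups()[3, ], seed = 7)
#' d <- generate_dataset(cfg)
#' d$samples
generate_dataset <- function(config) {
  stopifnot(inherits(config, "spad_generator_config"))
  if (!nrow(config$groups)) stop("empty group list")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  wl <- config$wavelengths
  base <- base_template(wl)
  absorb_fixed <- absorb_kernel(wl, carotenoid = 0)
  absorb_blue <- absorb_kernel(wl, carotenoid = 1) - absorb_fixed
  meta_l <- list(); spec_l <- list(); truth_l <- list()
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups[gi, ]
    n <- g$n
    spad <- rnorm_trunc(n, g$spad_mean, g$spad_sd, 0, 100)
    chl <- chl_from_spad(spad)
    gain <- 1 + rnorm(n, 0, config$scatter_gain_sd) +
      config$gain_spad_coupling * (spad - g$spad_mean) / g$spad_sd
    offset <- rnorm(n, 0, config$scatter_offset_sd)
    slope <- rnorm(n, 0, config$baseline_slope_sd)
    curv <- rnorm(n, 0, config$baseline_curv_sd)
    car <- exp(rnorm(n, 0, config$carotenoid_sd))
    u <- (wl - 700) / 375
    spec <- matrix(0, n, length(wl))
    for (i in seq_len(n)) {
      r <- gain[i] * (base - chl[i] * (absorb_fixed + car[i] * absorb_blue)) +
        offset[i] + slope[i] * u + curv[i] * u^2
      if (config$noise_sd > 0) r <- r + rnorm(length(wl), 0, config$noise_sd)
      spec[i, ] <- pmin(pmax(r, 1e-6), 1 - 1e-6)
    }
    n_out <- round(config$outlier_fraction * n)
    is_out <- rep(FALSE, n)
    kind <- rep(NA_character_, n)
    spad_rec <- spad
    if (n_out > 0) {
      pick <- sample.int(n, n_out)
      is_out[pick] <- TRUE
      kind[pick] <- switch(config$outlier_type,
                           spad = "spad", spectral = "spectral",
                           spike = "spike", gain = "gain",
                           mixed = sample(c("spad", "spectral"), n_out,
                                          replace = TRUE))
      for (i in pick) {
        if (kind[i] == "spad") {
          shift <- runif(1, 5, 8) * g$spad_sd * sample(c(-1, 1), 1)
          if (spad[i] + shift <= 0 || spad[i] + shift >= 100) shift <- -shift
          spad_rec[i] <- min(max(spad[i] + shift, 0.5), 99.5)
        } else if (kind[i] == "gain") {
          spec[i, ] <- pmin(pmax(spec[i, ] * 2, 1e-6), 1 - 1e-6)
        } else if (kind[i] == "spike") {
          ctr <- runif(1, 660, 730)
          amp <- sample(c(-1, 1), 1) * 0.2
          spike <- amp * exp(-0.5 * ((wl - ctr) / 12)^2)
          spec[i, ] <- pmin(pmax(spec[i, ] + spike, 1e-6), 1 - 1e-6)
        } else {
          # mispaired spectrum: the spectrum of a different leaf whose
          # latent chlorophyll sits a fixed 0.45 away (12-20 SPAD units,
          # i.e. around or beyond 5 group SDs for typical groups),
          # displaced toward the interior of the group range so the
          # spectrum stays physically valid and displacement directions
          # stay balanced (coherent one-sided contamination would bias
          # the PLSR fit itself and mask the planted outliers). All leaf
          # properties (including the SPAD-coupled gain) are re-rendered
          # consistently with the mispaired leaf.
          chl_bad <- chl[i] +
            0.45 * (if (chl[i] < chl_from_spad(g$spad_mean)) 1 else -1)
          spad_bad <- log(chl_bad / 0.12) / 0.035
          gain_bad <- 1 + rnorm(1, 0, config$scatter_gain_sd) +
            config$gain_spad_coupling * (spad_bad - g$spad_mean) / g$spad_sd
          r <- gain_bad * (base - chl_bad *
                             (absorb_fixed + car[i] * absorb_blue)) +
            offset[i] + slope[i] * u + curv[i] * u^2
          if (config$noise_sd > 0)
            r <- r + rnorm(length(wl), 0, config$noise_sd)
          spec[i, ] <- pmin(pmax(r, 1e-6), 1 - 1e-6)
        }
      }
    }
    ids <- sprintf("%s_%s_%03d", g$stage, g$leaf_position, seq_len(n))
    k <- seq_len(n)
    meta_l[[gi]] <- data.frame(
      sample_id = ids, stage = g$stage, leaf_position = g$leaf_position,
      variety = config$varieties[1 + (k - 1) %% length(config$varieties)],
      nitrogen = config$nitrogen[1 + ((k - 1) %/% length(config$varieties)) %%
                                   length(config$nitrogen)],
      spad = spad_rec, stringsAsFactors = FALSE)
    spec_l[[gi]] <- spec
    truth_l[[gi]] <- data.frame(
      sample_id = ids, latent_chlorophyll = chl, gain = gain, offset = offset,
      baseline_slope = slope, baseline_curv = curv, carotenoid = car,
      is_planted_outlier = is_out, outlier_kind = kind,
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta_l)
  spec <- do.call(rbind, spec_l)
  truth <- do.call(rbind, truth_l)
  samples <- spad_samples(meta, spec, wl, chain = "raw",
                          provenance = sprintf("generate_dataset(seed = %d)",
                                               config$seed))
  structure(list(samples = samples, truth = truth, config = config),
            class = "spad_synthetic")
}

#' @export
print.spad_synthetic <- function(x, ...) {
  cat("Synthetic SPAD/spectra dataset (seed", x$config$seed, ")\n")
  cat(sum(x$truth$is_planted_outlier), "planted outlier(s)\n")
  print(x$samples)
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
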