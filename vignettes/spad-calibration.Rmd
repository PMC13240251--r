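---
title: "Calibrating leaf SPAD against hyperspectral reflectance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating leaf SPAD against hyperspectral reflectance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadspec)
```

## The problem

SPAD meters give a fast, nondestructive reading of relative leaf
chlorophyll, widely used to steer nitrogen management in maize. Pairing
SPAD readings with leaf reflectance spectra (325–1075 nm at 1 nm) lets one
calibrate spectral predictors of SPAD so that chlorophyll status can later
be inferred from spectra alone. `spadspec` implements the full calibration
workflow as it is practised in leaf-level chemometrics:

1. **Outlier screening** — a K-means/Euclidean distance rule on the SPAD
   values and a Monte-Carlo PLSR residual rule on the spectra, with
   *paired exclusion* of the union so the two data sides stay aligned.
2. **Preprocessing** — Savitzky–Golay smoothing, followed by SNV,
   SNV-detrend, or MSC, composed as the chains `SG`, `SG-SNV`,
   `SG-SNV-DT`, `SG-MSC`.
3. **Vegetation indices** — 21 nominal-band indices built from R450, R550,
   R670, R720 and R800, implemented exactly as printed in the source
   formula table (including nonstandard variants such as the SAVI with a
   2.5 factor and +0.5 term, and PVI as a difference minus half the sum).
4. **Correlation screening** — Pearson *r* of each index (and each raw
   band) with SPAD, per group, with descriptive magnitude classes
   (|r| ≤ 0.3 none, ≤ 0.5 weak, ≤ 0.8 significant, > 0.8 highly
   significant; boundaries to the lower class).
5. **Models** — single-index regressions (linear, quadratic, exponential
   `a·e^{bx}`, power `a·x^b`) reported in-sample, and a multi-index random
   forest on a deterministic SPXY 4:1 calibration/validation split.
6. **Evaluation** — R² in its squared-correlation form, RMSE with
   denominator *n*, and RPD = SD/RMSE with capability classes
   (< 1.0 extremely poor … > 2.5 excellent; boundary values to the lower
   class, since the printed bins are all strict inequalities).

Because the field campaign data behind this workflow are not publicly
deposited, the package ships a synthetic generator that reproduces the
statistical structure the workflow assumes, with retained ground truth, so
every stage is exercisable and testable.

## The synthetic leaf model

A spectrum is rendered as

```
reflectance(λ) = gain · (base(λ) − chl · absorb(λ)) + baseline(λ) + noise
```

* `base(λ)` is a smooth sigmoid rising from ~0.10 in the visible to a
  ~0.50 NIR plateau (midpoint 705 nm, width 28 nm).
* `absorb(λ)` is a fixed nonnegative kernel: a blue lobe (450 nm, σ 35), a
  weak green shoulder (550 nm, σ 55) and a red lobe at 700 nm (σ 30), all
  multiplied by a cosine ramp that reaches exactly zero at 750 nm. NIR
  reflectance therefore carries no direct chlorophyll signal.
* `baseline(λ)` is a per-leaf random quadratic in the scaled wavelength
  `u = (λ−700)/375` (offset, tilt, curvature), the smooth drift that the
  detrend step exists to remove; `gain` is per-leaf multiplicative
  scatter; `noise` is white.

Three design choices deserve comment, because each was genuinely open:

**The red lobe sits at 700 nm, not at the 670 nm absorption maximum.** The
kernel is the *linearised sensitivity* of reflectance to chlorophyll over
the working range. In mature green leaves the 660–680 nm core is optically
saturated — reflectance there barely responds to further chlorophyll — so
the usable sensitivity sits on the red-edge flank. Placing the lobe at
700 nm reproduces two robust field observations: the band-wise SPAD
correlogram attains its most negative value just short of the red edge
(~697 nm on default synthetic data, against ~710–712 nm reported for field
maize), and red-edge indices (NDRE, CIrededge) dominate the correlation
screening. A kernel peaked at 670 nm instead makes plain
difference indices unrealistically strong.

**The SPAD→chlorophyll link is exponential**, `chl = 0.12·exp(0.035·SPAD)`.
SPAD readings saturate at high chlorophyll, so latent chlorophyll grows
convexly with the reading; only monotonicity matters to the pipeline, but
the convexity also shapes which index families correlate most linearly
with SPAD, as in real data.

**Per-leaf pigment-ratio variation.** A lognormal factor (log-SD 0.3)
scales the accessory-pigment (400–550 nm) absorption. Without it, any
three-band visible combination can reconstruct chlorophyll nearly
noise-free, which no field dataset supports. The factor is exposed as the
`carotenoid` argument of `generate_spectrum()` and defaults to 1 (the
fixed kernel) there; the dataset generator draws it per leaf.

A weak positive coupling (0.02 per group SD) between the scatter gain and
SPAD emulates the mesophyll/thickness covariation that makes NIR
reflectance correlate positively (~+0.5) with SPAD in field data, while
`generate_spectrum()` itself keeps NIR independent of chlorophyll.

Default group design mirrors a replicated field campaign: nine
(stage × leaf position) groups of 219–229 leaves with SPAD means 50.6–61.7
and SDs 3.0–5.8 (all group CVs below 10%). SPAD is drawn from a Normal
truncated to (0, 100), the physical range of the meter. Scatter and noise
scales (`gain` SD 0.03, baseline offset/tilt/curvature SDs
0.012/0.01/0.008, white noise SD 0.003) are free parameters of the
emulation — no instrument noise figures are published for the original
campaign — chosen once to produce index–SPAD correlations in the 0.8–0.95
range after preprocessing, somewhat cleaner than the 0.7–0.8 reported on
field data.

## Planted outliers and what the screens can (and cannot) detect

The generator plants outliers of explicit kinds, flagged in the returned
truth *before* corruption:

* **`spad`** — the recorded SPAD is shifted by 5–8 group SDs (direction
  flipped if the shift would leave (0, 100)); the spectrum is untouched.
* **`spectral`** — the spectrum is replaced by that of a *mispaired* leaf:
  re-rendered from a latent chlorophyll displaced by a fixed 0.45
  (≈ 12–20 SPAD units), all leaf properties re-rendered consistently.
  This emulates SPAD and spectrum being read from different leaves or
  spots — the anomaly class paired exclusion exists for.
* **`spike`** — a band-localised artifact on the red/red-edge region.
* **`gain`** — gross gain doubling.

The default `spectral` kind is mispairing rather than gain doubling, and
this is a finding worth recording: a PLSR calibration trained on
scatter-rich spectra learns scale-invariant contrasts, so a gain-doubled
spectrum is predicted almost normally — a single planted gain×2 sample
ranks around 15th of 300 by residual statistic — and is correspondingly
almost harmless to the calibration. Conversely, spikes strong enough to
flag reliably also distort the fitted model itself at 5% contamination,
inflating everyone's residuals. A y-residual screen detects what
*mispredicts without deforming the model*: on-manifold mispairings. Their
displacement is applied toward the interior of the group range with
balanced directions, because a coherent one-sided contamination biases
the PLSR slope and masks the planted outliers.

The mispairing displacement is uniform in chlorophyll (where the spectral
model is linear) rather than in SPAD units: the single-pass
`mean + 3·SD` threshold prescribed for the residual statistics inflates
with the largest outliers, so heterogeneous planted magnitudes make
sensitivity erratic. Even so, at 5% contamination the rule operates near
its breakdown point; across probe seeds its sensitivity ranges roughly
0.73–1.00 (zero false positives), which is a property of the published
single-pass rule, not of the implementation.

## Numerical conventions

* Standard deviations use the n−1 denominator everywhere — pinned by the
  SNV example `snv(c(0.1, 0.2, 0.3)) = (−1, 0, 1)` — except RMSE, whose
  printed formula divides by n.
* R² is the squared Pearson correlation of predictions and observations,
  *not* 1 − SSE/SST; the two differ for offset-biased predictors, and the
  squared-correlation form is symmetric and affine-invariant.
* Index denominators with magnitude below 1e-10 yield masked (`NA`)
  entries rather than errors, because SNV/detrended spectra legitimately
  cross zero; masked pairs are dropped listwise in correlations and
  masked columns are dropped (and logged) before the random forest.
* Band lookup is nearest-wavelength with ties toward the lower wavelength;
  on the canonical 1 nm grid integer queries are exact.
* `spxy_split()` is fully deterministic: normalised X- and Y-distances are
  summed, the mutually farthest pair seeds the training set, and ties
  break toward the lowest row index.
* Savitzky–Golay defaults are window 15, order 2 — conventional for 1 nm
  leaf spectra from a 3 nm-resolution instrument; the detrend default is
  degree 2, the standard SNV-detrend pairing. Edges are served by the
  first/last full-window fit, so polynomials up to the filter order are
  reproduced exactly everywhere.
* The Monte-Carlo PLSR screen uses SIMPLS (univariate response), 10-fold
  cross-validation capped at 20 components, 1000 iterations by default
  with an 80% calibration fraction drawn without replacement, and flags
  on the per-sample mean absolute residual; residuals are computed for
  all samples each iteration (`heldout_only = FALSE`), matching the
  published description, with held-out-only aggregation available.
* The random forest tunes ensemble size over {5, 10, 50, 100, 200, 500,
  1000} and `mtry` over 1..⌊2p/3⌋ by out-of-bag error on the training
  partition.
* K-means screening defaults to k = 1, where the rule degenerates to the
  plain centre-distance rule (SPAD is screened univariately per group);
  k is configurable.

## Order of operations and leakage

`run_full_pipeline()` follows the published order: screen → preprocess the
whole group → compute indices → correlate → split (SPXY) → model. The MSC
reference is therefore computed from the full group before the split, and
the SPXY partition itself sees all samples. This mild leakage is inherent
to the published design; for leakage-free deployment, `apply_chain()`
accepts a frozen MSC reference (recorded in the attribute
`msc_reference` of a calibration run) so held-out data can be transformed
with calibration statistics only — the mechanism is tested, but the
pipeline reproduces the published order.

## What passing tests do and do not show

The generator emulates: group-wise SPAD moments with CVs below 10%,
monotone SPAD–chlorophyll coupling with the correct correlation signs
(negative through the visible, positive in the NIR), multiplicative and
smooth additive scatter removable by SNV/MSC/detrend, pigment-ratio
nuisance variation, and gross planted anomalies. It does **not** emulate:
canopy/BRDF and illumination-geometry effects, water and dry-matter
absorption beyond 950 nm, instrument-specific splice artifacts, variety- or
nitrogen-specific response differences, or spatial correlation between
neighbouring plots. Tests passing on synthetic data therefore validate the
*machinery* (formulas, rules, determinism, recovery of planted structure),
not field-level accuracy claims; synthetic correlations and R² run
noticeably higher than the field-reported values, as expected for a
cleaner world.

Problem sizes used by the test-suite and the acceptance script were chosen
to keep the full run in minutes on a single core: 300-leaf groups for the
outlier benchmarks with 200 Monte-Carlo iterations (the package default
remains 1000), the full nine-group design (~2000 leaves) for screening
checks, and a single group for random-forest fits.

## Known limitations

* The single-pass 3·SD residual threshold sits near its breakdown point at
  5% structured contamination (see above); an iterated or robust
  (median/MAD) variant would be more stable but is deliberately not the
  default, to match the published procedure.
* Exponential/power single-index fits require positive responses
  (SPAD > 0 always holds) and, for the power form, strictly positive
  index values; preprocessed indices that cross zero return a
  `not_fittable` status rather than an error.
* RPD classes are reported from the printed strict-inequality bins;
  values falling exactly on an edge go to the lower class, an explicit
  convention since the bins leave edges unassigned.
* The correlation magnitude classes are descriptive bins, not hypothesis
  tests; no p-values or multiplicity control are computed for the
  screening grid.
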