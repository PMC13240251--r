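# Spectral preprocessing: Savitzky-Golay smoothing plus the three
# scatter-correction treatments (SNV, detrend, MSC) and their composition
# into the chains applied on top of SG smoothing.

#' Savitzky-Golay convolution smoothing
#'
#' Local least-squares polynomial smoothing. Interior points use the
#' centred window; the first and last half-windows are served by the
#' polynomial fitted to the first/last full window, so polynomials up to
#' `polyorder` are reproduced exactly everywhere.
#'
#' @param x numeric vector (one spectrum) or samples-x-bands matrix.
#' @param window odd window length (bands), default 15.
#' @param polyorder polynomial order, default 2; must be < `window`.
#' @return smoothed object of the same shape.
#' @export
sg_smooth <- function(x, window = 15, polyorder = 2) {
  stopifnot(window %% 2 == 1, polyorder < window)
  if (is.matrix(x)) {
    if (window > ncol(x)) stop("window longer than the spectrum")
    out <- t(apply(x, 1, signal::sgolayfilt, p = polyorder, n = window))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (window > length(x)) stop("window longer than the spectrum")
  out <- signal::sgolayfilt(x, p = polyorder, n = window)
  names(out) <- names(x)
  out
}

#' Standard normal variate (SNV) transform
#'
#' Centres and scales each spectrum to zero mean and unit standard
#' deviation (n - 1 denominator), removing per-spectrum gain and offset.
#'
#' @param x numeric vector or samples-x-bands matrix.
#' @return transformed object of the same shape.
#' @export
#' @examples
#' snv(c(0.1, 0.2, 0.3))  # -1 0 1
snv <- function(x) {
  f <- function(v) {
    s <- sd(v)
    if (s == 0) stop("SNV undefined for a constant spectrum")
    (v - mean(v)) / s
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, f)); dimnames(out) <- dimnames(x); out
  } else f(x)
}

#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial of the given degree fitted to
#' reflectance as a function of wavelength, removing smooth baseline drift;
#' the residual spectrum has mean ~0 and is orthogonal to the fitted basis.
#'
#' @param x numeric vector or samples-x-bands matrix.
#' @param wavelengths nm grid matching the bands.
#' @param degree polynomial degree >= 1, default 2.
#' @return detrended object of the same shape.
#' @export
detrend <- function(x, wavelengths, degree = 2) {
  stopifnot(degree >= 1)
  nb <- if (is.matrix(x)) ncol(x) else length(x)
  stopifnot(length(wavelengths) == nb, degree < nb)
  B <- cbind(1, poly(as.numeric(wavelengths), degree))
  qrB <- qr(B)
  f <- function(v) qr.resid(qrB, v)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, f)); dimnames(out) <- dimnames(x); out
  } else {
    out <- f(x); names(out) <- names(x); out
  }
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum `x` is regressed on a reference spectrum over the bands,
#' `x = a + b * ref`, and corrected as `(x - a) / b`, inverting additive and
#' multiplicative scatter. The reference defaults to the mean spectrum of
#' the input set and is attached to the result (attribute
#' `"msc_reference"`) so a calibration reference can be reused on new data.
#'
#' @param x samples-x-bands matrix (or a single spectrum when an explicit
#'   `reference` is supplied).
#' @param reference `"mean"` or a numeric reference spectrum.
#' @return corrected matrix (or vector) with attribute `msc_reference`.
#' @export
msc <- function(x, reference = "mean") {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  if (identical(reference, "mean")) {
    if (nrow(x) < 2)
      stop("mean reference needs at least 2 spectra")
    reference <- colMeans(x)
  }
  stopifnot(length(reference) == ncol(x))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- x
  for (i in seq_len(nrow(x))) {
    b <- sum((x[i, ] - mean(x[i, ])) * rc) / denom
    if (abs(b) < 1e-8)
      stop("MSC slope ~0 for spectrum ", i, "; correction undefined")
    a <- mean(x[i, ]) - b * mean(reference)
    out[i, ] <- (x[i, ] - a) / b
  }
  if (vec) out <- out[1, ]
  attr(out, "msc_reference") <- reference
  out
}

#' Define a preprocessing chain
#'
#' Valid steps are `SG`, `SNV`, `DT`, `MSC`; when present, `SG` must come
#' first (the scatter treatments are applied on top of SG smoothing). The
#' canonical chains are `SG`, `SG-SNV`, `SG-SNV-DT` and `SG-MSC`.
#'
#' @param steps character vector of steps, or a single dash-separated tag
#'   such as `"SG-SNV-DT"`.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param dt_degree detrend polynomial degree.
#' @param msc_reference `"mean"` or a frozen numeric reference spectrum.
#' @return object of class `spad_chain`.
#' @export
preprocessing_chain <- function(steps, sg_window = 15, sg_polyorder = 2,
                                dt_degree = 2, msc_reference = "mean") {
  if (length(steps) == 1 && grepl("-", steps))
    steps <- strsplit(steps, "-", fixed = TRUE)[[1]]
  steps <- toupper(steps)
  bad <- setdiff(steps, c("SG", "SNV", "DT", "MSC"))
  if (length(bad)) stop("unknown preprocessing step(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(steps)) stop("repeated preprocessing step")
  if ("SG" %in% steps && which(steps == "SG") != 1L)
    stop("SG smoothing, if present, must be the first step")
  structure(list(steps = steps, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, dt_degree = dt_degree,
                 msc_reference = msc_reference,
                 tag = paste(steps, collapse = "-")),
            class = "spad_chain")
}

#' @export
print.spad_chain <- function(x, ...) {
  cat("preprocessing chain:", x$tag, "\n")
  invisible(x)
}

#' Apply a preprocessing chain to a sample set
#'
#' Steps are applied in order to every spectrum; the set's `chain` tag is
#' updated and, when MSC is involved, the reference spectrum actually used
#' is recorded in the result's provenance-carrying attribute
#' `msc_reference` for reuse on held-out data.
#'
#' @param samples `spad_samples` object.
#' @param chain `spad_chain`, or anything [preprocessing_chain()] accepts.
#' @return preprocessed `spad_samples` (same grid and sample count).
#' @export
#' @examples
#' cfg <- generator_config(groups = default_groups()[1, ], seed = 1)
#' d <- generate_dataset(cfg)
#' pp <- apply_chain(d$samples, "SG-SNV")
#' pp$chain
apply_chain <- function(samples, chain) {
  stopifnot(inherits(samples, "spad_samples"))
  if (!inherits(chain, "spad_chain")) chain <- preprocessing_chain(chain)
  m <- samples$spectra
  msc_ref <- NULL
  for (st in chain$steps) {
    m <- switch(st,
      SG = sg_smooth(m, chain$sg_window, chain$sg_polyorder),
      SNV = snv(m),
      DT = detrend(m, samples$wavelengths, chain$dt_degree),
      MSC = {
        mm <- msc(m, chain$msc_reference)
        msc_ref <- attr(mm, "msc_reference")
        attr(mm, "msc_reference") <- NULL
        mm
      })
  }
  out <- spad_samples(samples$meta, m, samples$wavelengths,
                      chain = chain$tag,
                      provenance = c(samples$provenance,
                                     paste("apply_chain:", chain$tag)))
  if (!is.null(msc_ref)) attr(out, "msc_reference") <- msc_ref
  out
}
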