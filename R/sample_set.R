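#' Construct a sample set of paired leaf spectra and SPAD readings
#'
#' `spad_samples` is the container that flows through the whole workflow: an
#' aligned collection of per-leaf reflectance spectra, SPAD values and group
#' metadata (growth stage, leaf position, variety, nitrogen rate).
#'
#' @param meta data.frame with columns `sample_id`, `stage` (one of V6, V8,
#'   V12, R1, R2), `leaf_position` (apical, upper_ear, ear, lower_ear),
#'   `variety`, `nitrogen` (N0, N2, N4) and `spad` (SPAD units, in (0, 100)).
#' @param spectra numeric matrix, samples x wavelengths; row order must match
#'   `meta`. Column names (or `wavelengths`) give the nm grid.
#' @param wavelengths integer wavelength grid (nm), strictly increasing at
#'   1 nm. Defaults to the numeric column names of `spectra`.
#' @param chain preprocessing tag; `"raw"` for untreated reflectance. Raw
#'   spectra must lie in \[0, 1\]; preprocessed spectra are unrestricted.
#' @param provenance character log of operations applied so far.
#'
#' @return An object of class `spad_samples` with elements `meta`, `spectra`,
#'   `wavelengths`, `chain`, `provenance`.
#' @export
#' @examples
#' wl <- 325:1075
#' sp <- matrix(runif(2 * length(wl), 0.1, 0.5), 2, dimnames = list(NULL, wl))
#' meta <- data.frame(sample_id = c("a", "b"), stage = "V6",
#'                    leaf_position = "apical", variety = "ZD958",
#'                    nitrogen = "N2", spad = c(50, 55))
#' ss <- spad_samples(meta, sp)
#' ss
spad_samples <- function(meta, spectra, wavelengths = NULL, chain = "raw",
                         provenance = character()) {
  stopifnot(is.data.frame(meta), is.matrix(spectra))
  need <- c("sample_id", "stage", "leaf_position", "variety", "nitrogen", "spad")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("meta is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(spectra))
    stop("meta has ", nrow(meta), " rows but spectra has ", nrow(spectra))
  if (is.null(wavelengths)) {
    if (is.null(colnames(spectra)))
      stop("wavelengths must be given when spectra has no column names")
    wavelengths <- as.numeric(colnames(spectra))
  }
  wavelengths <- as.integer(round(wavelengths))
  check_grid(wavelengths)
  if (length(wavelengths) != ncol(spectra))
    stop("wavelength grid length does not match spectra columns")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (anyNA(spectra)) stop("spectra contain missing values")
  if (!is.numeric(spectra)) stop("spectra must be numeric")
  if (identical(chain, "raw")) {
    bad <- which(spectra < 0 | spectra > 1, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("raw reflectance outside [0,1]: sample '%s', wavelength %d nm (value %.4g)",
                   meta$sample_id[bad[1, 1]], wavelengths[bad[1, 2]],
                   spectra[bad[1, 1], bad[1, 2]]))
  }
  if (!all(meta$stage %in% STAGE_LEVELS))
    stop("unknown stage label(s): ",
         paste(setdiff(unique(meta$stage), STAGE_LEVELS), collapse = ", "))
  if (!all(meta$leaf_position %in% LEAF_LEVELS))
    stop("unknown leaf_position label(s): ",
         paste(setdiff(unique(meta$leaf_position), LEAF_LEVELS), collapse = ", "))
  ok <- mapply(function(s, l) l %in% VALID_STAGE_LEAF[[s]],
               meta$stage, meta$leaf_position)
  if (!all(ok))
    stop("invalid stage/leaf_position pairing for sample(s): ",
         paste(head(meta$sample_id[!ok], 5), collapse = ", "))
  if (any(meta$spad <= 0 | meta$spad >= 100))
    stop("SPAD values must lie in (0, 100)")
  dimnames(spectra) <- list(meta$sample_id, wavelengths)
  structure(list(meta = meta, spectra = spectra, wavelengths = wavelengths,
                 chain = chain, provenance = provenance),
            class = "spad_samples")
}

check_grid <- function(wl) {
  if (length(wl) < 2 || any(diff(wl) != 1L))
    stop("wavelength grid must be strictly increasing with a 1 nm step")
  invisible(wl)
}

#' @export
print.spad_samples <- function(x, ...) {
  cat(sprintf("spad_samples: %d samples, %d bands (%d-%d nm), chain '%s'\n",
              nrow(x$meta), length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$chain))
  tab <- table(x$meta$stage, x$meta$leaf_position)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  print(tab)
  invisible(x)
}

#' @export
summary.spad_samples <- function(object, ...) group_summary(object)

#' Subset a sample set
#'
#' @param x `spad_samples` object.
#' @param i integer/logical index or character vector of sample ids.
#' @param ... unused.
#' @return `spad_samples` containing the selected samples.
#' @export
`[.spad_samples` <- function(x, i, ...) {
  if (is.character(i)) {
    pos <- match(i, x$meta$sample_id)
    if (anyNA(pos)) stop("unknown sample id(s): ",
                         paste(i[is.na(pos)], collapse = ", "))
    i <- pos
  }
  spad_samples(x$meta[i, , drop = FALSE],
               x$spectra[i, , drop = FALSE],
               x$wavelengths, chain = x$chain, provenance = x$provenance)
}

#' Number of samples in a set
#' @param x `spad_samples` object.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$meta)

#' Reflectance at a nominal wavelength
#'
#' Looks up reflectance at the grid wavelength nearest to `wavelength`
#' (ties broken toward the lower wavelength); on the 1 nm grid an integer
#' query is an exact match. This is the `R_s` accessor the vegetation-index
#' formulas are written in.
#'
#' @param x `spad_samples` object (returns a per-sample vector) or a numeric
#'   reflectance vector accompanied by `wavelengths`.
#' @param wavelength query wavelength in nm; must lie within the grid span.
#' @param wavelengths grid for the vector method; ignored for `spad_samples`.
#' @return Named numeric vector (one value per sample), or a scalar for a
#'   single spectrum vector.
#' @export
#' @examples
#' band(c(0.1, 0.2, 0.3), 801, wavelengths = 800:802)
band <- function(x, wavelength, wavelengths = NULL) {
  if (inherits(x, "spad_samples")) {
    j <- band_index(x$wavelengths, wavelength)
    return(x$spectra[, j])
  }
  stopifnot(is.numeric(x), !is.null(wavelengths),
            length(x) == length(wavelengths))
  x[band_index(wavelengths, wavelength)]
}

band_index <- function(grid, wavelength) {
  stopifnot(length(wavelength) == 1, is.finite(wavelength))
  if (wavelength < min(grid) || wavelength > max(grid))
    stop(sprintf("wavelength %.1f nm outside grid span %d-%d nm",
                 wavelength, min(grid), max(grid)))
  d <- abs(grid - wavelength)
  which(d == min(d))[1L]  # ties toward the lower wavelength
}

#' Read a paired spectra + SPAD sample set from CSV
#'
#' Joins a wide spectra table (rows = samples, columns = wavelengths, first
#' column `sample_id`; or long format with columns `sample_id`, `wavelength`,
#' `reflectance`) against a SPAD/metadata table keyed by `sample_id`. Samples
#' present on only one side are dropped with a warning and a provenance log
#' entry, mirroring paired exclusion.
#'
#' @param spectra_path CSV of reflectance spectra.
#' @param spad_path CSV with columns `sample_id`, `stage`, `leaf_position`,
#'   `variety`, `nitrogen`, `spad`.
#' @param format `"wide"` (canonical) or `"long"` (read-only convenience).
#' @param chain preprocessing tag of the stored spectra (default `"raw"`).
#' @return `spad_samples` object.
#' @seealso [write_sample_set()]
#' @export
read_sample_set <- function(spectra_path, spad_path, format = c("wide", "long"),
                            chain = "raw") {
  format <- match.arg(format)
  spec_df <- read.csv(spectra_path, check.names = FALSE)
  meta <- read.csv(spad_path, check.names = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in SPAD table")
  if (format == "wide") {
    ids <- as.character(spec_df[[1L]])
    m <- as.matrix(spec_df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(spec_df[-1L], is.numeric, logical(1)))[1L]
      stop("non-numeric reflectance in column '", names(spec_df)[bad + 1L], "'")
    }
    wl <- as.numeric(colnames(m))
    if (anyNA(wl)) stop("spectra columns must be named by wavelength (nm)")
    rownames(m) <- ids
  } else {
    need <- c("sample_id", "wavelength", "reflectance")
    if (!all(need %in% names(spec_df)))
      stop("long format needs columns: ", paste(need, collapse = ", "))
    wl <- sort(unique(spec_df$wavelength))
    ids <- unique(as.character(spec_df$sample_id))
    m <- matrix(NA_real_, length(ids), length(wl),
                dimnames = list(ids, wl))
    m[cbind(match(as.character(spec_df$sample_id), ids),
            match(spec_df$wavelength, wl))] <- spec_df$reflectance
    if (anyNA(m)) stop("long spectra table does not cover a full common grid")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate sample_id in spectra table")
  common <- intersect(rownames(m), meta$sample_id)
  dropped <- (nrow(m) - length(common)) + (nrow(meta) - length(common))
  prov <- character()
  if (dropped > 0) {
    warning(dropped, " unpaired sample(s) dropped during spectra/SPAD join")
    prov <- sprintf("read_sample_set: dropped %d unpaired sample(s)", dropped)
  }
  if (!length(common)) stop("no sample_id overlap between the two files")
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]
  spad_samples(meta, m[common, , drop = FALSE], wl, chain = chain,
               provenance = prov)
}

#' Write a sample set to paired CSV files
#'
#' Inverse of [read_sample_set()] (wide dialect): values round-trip to
#' full double precision.
#'
#' @param x `spad_samples` object.
#' @param spectra_path,spad_path output CSV paths.
#' @return `x`, invisibly.
#' @export
write_sample_set <- function(x, spectra_path, spad_path) {
  stopifnot(inherits(x, "spad_samples"))
  df <- data.frame(sample_id = x$meta$sample_id, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$spectra, check.names = FALSE))
  # 17 significant digits preserve doubles exactly through text
  old <- options(digits = 17); on.exit(options(old))
  write.csv(df, spectra_path, row.names = FALSE, quote = FALSE)
  write.csv(x$meta, spad_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Split a sample set by (stage, leaf position) group
#'
#' @param x `spad_samples` object.
#' @return Named list of `spad_samples`, one per group present, names
#'   `"stage/leaf_position"`.
#' @export
split_groups <- function(x) {
  key <- paste(x$meta$stage, x$meta$leaf_position, sep = "/")
  idx <- split(seq_len(nrow(x$meta)), key)
  lapply(idx, function(i) x[i])
}
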