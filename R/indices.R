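# The 21 nominal-band vegetation indices, implemented exactly as printed in
# the source formula table (including its nonstandard variants, e.g. SAVI
# with the 2.5 factor and +0.5 term, CCI2 with +0.1, PVI as a difference
# minus half the sum). Bands used: R450, R550, R670, R720, R800.

# Each entry maps named band vectors to (numerator, denominator); a
# denominator with |den| < 1e-10 masks the value as NA rather than erroring,
# since preprocessed spectra legitimately cross zero.
INDEX_DEFS <- list(
  ARVI      = function(b) list((b$R800 - (2 * b$R670 - b$R450)),
                               (b$R800 + b$R670 + 0.5)),
  CARI      = function(b) list((b$R670 - b$R450) - (b$R670 - b$R800), NULL),
  CCI2      = function(b) list((b$R800 - b$R670),
                               (b$R800 + b$R670 + 0.1)),
  CIgreen   = function(b) list(b$R800, b$R550, offset = -1),
  CIrededge = function(b) list(b$R800, b$R720, offset = -1),
  CNDVI     = function(b) list((b$R800 - b$R670) - (b$R800 - b$R450),
                               (b$R800 - b$R670) + (b$R800 - b$R450)),
  CVI       = function(b) list(b$R800^2, b$R670),
  CVI2      = function(b) list(b$R800, (b$R720 + 1)),
  DVI       = function(b) list(b$R800 - b$R670, NULL),
  EVI       = function(b) list(2.5 * (b$R800 - b$R670),
                               (b$R800 + 6 * b$R670 - 7.5 * b$R450 + 1)),
  GNDVI     = function(b) list((b$R800 - b$R550), (b$R800 + b$R550)),
  MCARI     = function(b) list((b$R670 - b$R450) - (b$R670 - b$R800),
                               b$R670),
  NDRE      = function(b) list((b$R800 - b$R720), (b$R800 + b$R720)),
  NDVI      = function(b) list((b$R800 - b$R670), (b$R800 + b$R670)),
  NLI       = function(b) list(b$R800, (b$R670 + b$R550)),
  PVI       = function(b) list((b$R800 - b$R670) - 0.5 * (b$R800 + b$R670),
                               NULL),
  RVI       = function(b) list(b$R800, b$R670),
  SAVI      = function(b) list(2.5 * (b$R800 - b$R670),
                               (b$R800 + b$R670 + 0.5)),
  TGI       = function(b) list(b$R550 - 0.39 * b$R670 - 0.61 * b$R450, NULL),
  VARI      = function(b) list((b$R550 - b$R670),
                               (b$R550 + b$R670 - b$R450)),
  VIG       = function(b) list((b$R800 - (2 * b$R670 + b$R450)),
                               (b$R800 + (2 * b$R670 + b$R450)))
)

#' Names of the 21 vegetation indices
#' @return character vector in the fixed column order.
#' @export
index_names <- function() names(INDEX_DEFS)

eval_index <- function(name, bands) {
  def <- INDEX_DEFS[[name]]
  if (is.null(def)) stop("unknown index name: ", name)
  parts <- def(bands)
  num <- parts[[1]]
  den <- parts[[2]]
  off <- if (length(parts) >= 3) parts[[3]] else 0
  if (is.null(den)) return(num + off)
  ifelse(abs(den) < 1e-10, NA_real_, num / den + off)
}

#' Compute one vegetation index
#'
#' @param x `spad_samples` object (vector result, one value per sample) or
#'   a named list/data.frame of band vectors `R450`, `R550`, `R670`,
#'   `R720`, `R800`.
#' @param name one of [index_names()].
#' @return numeric vector; entries are `NA` (masked) where a denominator
#'   magnitude falls below 1e-10.
#' @export
#' @examples
#' compute_index(list(R450 = 0.05, R550 = 0.1, R670 = 0.1, R720 = 0.3,
#'                    R800 = 0.5), "RVI")  # 5
compute_index <- function(x, name) {
  bands <- extract_bands(x)
  eval_index(name, bands)
}

extract_bands <- function(x) {
  if (inherits(x, "spad_samples")) {
    b <- lapply(NOMINAL_BANDS, function(w) band(x, w))
    names(b) <- paste0("R", NOMINAL_BANDS)
    b
  } else if (is.list(x)) {
    need <- paste0("R", NOMINAL_BANDS)
    if (!all(need %in% names(x)))
      stop("band list must contain: ", paste(need, collapse = ", "))
    x
  } else stop("x must be a spad_samples object or a named band list")
}

#' Compute the full samples-by-21 index table
#'
#' @param samples `spad_samples` object (typically preprocessed).
#' @return object of class `spad_index_table`: a list with `values`
#'   (samples x 21 matrix, fixed column order), `sample_ids`, `chain`, and
#'   `masked` (data.frame logging any masked sample/index pairs).
#' @export
compute_index_table <- function(samples) {
  stopifnot(inherits(samples, "spad_samples"), nrow(samples$meta) >= 1)
  bands <- extract_bands(samples)
  vals <- vapply(index_names(), function(nm) eval_index(nm, bands),
                 numeric(nrow(samples$meta)))
  if (nrow(samples$meta) == 1) vals <- matrix(vals, 1,
                                              dimnames = list(NULL, index_names()))
  rownames(vals) <- samples$meta$sample_id
  mi <- which(is.na(vals), arr.ind = TRUE)
  masked <- data.frame(sample_id = rownames(vals)[mi[, 1]],
                       index = colnames(vals)[mi[, 2]],
                       stringsAsFactors = FALSE)
  structure(list(values = vals, sample_ids = samples$meta$sample_id,
                 chain = samples$chain, masked = masked),
            class = "spad_index_table")
}

#' @export
print.spad_index_table <- function(x, ...) {
  cat(sprintf("index table: %d samples x %d indices (chain '%s'), %d masked\n",
              nrow(x$values), ncol(x$values), x$chain, nrow(x$masked)))
  invisible(x)
}

#' @export
as.data.frame.spad_index_table <- function(x, ...) {
  cbind(data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE),
        as.data.frame(x$values))
}
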