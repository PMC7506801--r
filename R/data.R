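#' Construct a spectra dataset
#'
#' Bundles an `n x m` predictor matrix (absorbance spectra or simulated
#' covariates) with an `n`-vector response and optional per-column
#' wavelength labels. All downstream fitting, scoring and selection
#' functions operate on this container.
#'
#' @param X numeric matrix, samples in rows, wavelengths in columns.
#' @param y numeric response vector, one value per row of `X`.
#' @param wavelengths optional vector of column labels (nm for real
#'   spectra); numeric where possible.
#' @return An object of class `spectra_dataset` with elements `X`, `y`
#'   and `wavelengths`.
#' @export
spectra_dataset <- function(X, y, wavelengths = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2L)
    stop("spectra_dataset: need at least 2 samples, got ", nrow(X))
  if (length(y) != nrow(X))
    stop("spectra_dataset: length(y) [", length(y),
         "] does not match nrow(X) [", nrow(X), "]")
  if (anyNA(X) || anyNA(y))
    stop("spectra_dataset: missing values are not allowed")
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != ncol(X))
      stop("spectra_dataset: ", length(wavelengths),
           " wavelength labels for ", ncol(X), " columns")
    if (anyDuplicated(wavelengths))
      stop("spectra_dataset: duplicate wavelength labels")
    colnames(X) <- as.character(wavelengths)
  }
  structure(list(X = X, y = y, wavelengths = wavelengths),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("spectra_dataset: ", nrow(x$X), " samples x ", ncol(x$X),
      " wavelengths\n", sep = "")
  if (!is.null(x$wavelengths))
    cat("  labels: ", as.character(x$wavelengths[1L]), " ... ",
        as.character(x$wavelengths[length(x$wavelengths)]), "\n", sep = "")
  cat("  response range: [", format(min(x$y)), ", ", format(max(x$y)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$X)

# internal: coerce matrix-like + y into spectra_dataset unless already one
as_spectra_dataset <- function(data) {
  if (inherits(data, "spectra_dataset")) return(data)
  stop("expected a spectra_dataset; see spectra_dataset()")
}
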