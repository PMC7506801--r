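#' Read a spectra dataset from CSV files
#'
#' `x_path` must be a comma-separated file with a header row of
#' wavelength labels (parsed as numbers when possible) and one sample
#' per row; `y_path` a single-column CSV (header optional) with one
#' reference value per sample.
#'
#' @param x_path path to the predictor CSV.
#' @param y_path path to the response CSV.
#' @param transpose set `TRUE` for wavelength-major exports (rows =
#'   wavelengths) as produced by some instrument software.
#' @return A [spectra_dataset()].
#' @export
read_spectra <- function(x_path, y_path, transpose = FALSE) {
  xdf <- utils::read.csv(x_path, header = TRUE, check.names = FALSE)
  X <- as.matrix(xdf)
  if (transpose) X <- t(X)
  if (!is.numeric(X))
    stop("read_spectra: non-numeric cells in ", x_path)
  labels <- colnames(X)
  if (anyDuplicated(labels))
    stop("read_spectra: duplicate wavelength labels in ", x_path)
  num <- suppressWarnings(as.numeric(labels))
  wl <- if (!anyNA(num)) num else labels

  ydf <- utils::read.csv(y_path, header = TRUE)
  if (ncol(ydf) != 1L)
    stop("read_spectra: ", y_path, " must have exactly one column")
  y <- ydf[[1L]]
  if (!is.numeric(y)) {
    # tolerate headerless single-column files
    ydf <- utils::read.csv(y_path, header = FALSE)
    y <- ydf[[1L]]
  }
  if (!is.numeric(y)) stop("read_spectra: non-numeric response in ", y_path)
  if (length(y) != nrow(X))
    stop("read_spectra: X has ", nrow(X), " rows but y has ",
         length(y), " values")
  spectra_dataset(X, y, wl)
}

#' Write a spectra dataset as CSV files
#'
#' Inverse of [read_spectra()]: the predictor matrix with a wavelength
#' header row and a single-column response file.
#'
#' @param data a [spectra_dataset()].
#' @param x_path,y_path output paths.
#' @return `invisible(data)`.
#' @export
write_spectra <- function(data, x_path, y_path) {
  data <- as_spectra_dataset(data)
  X <- data$X
  colnames(X) <- if (is.null(data$wavelengths))
    paste0("v", seq_len(ncol(X))) else as.character(data$wavelengths)
  utils::write.csv(as.data.frame(X), x_path, row.names = FALSE)
  utils::write.csv(data.frame(y = data$y), y_path, row.names = FALSE)
  invisible(data)
}

#' Read a run configuration from YAML or JSON
#'
#' Accepts either file flavour (chosen by extension) and validates that
#' exactly one of an input block (`x`, `y` paths) or a simulation block
#' (`n`, `m`, `iv_fraction`) is present.
#'
#' @param path configuration file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    # keep bare n/y keys as strings (YAML 1.1 would read them as booleans)
    yaml::read_yaml(path, handlers = list("bool#no" = identity,
                                          "bool#yes" = identity))
  else jsonlite::read_json(path, simplifyVector = TRUE)
  has_input <- !is.null(cfg$x) && !is.null(cfg$y)
  has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim)
    stop("read_run_config: exactly one of {x/y input paths, simulate block} ",
         "must be present")
  if (has_input && (!file.exists(cfg$x) || !file.exists(cfg$y)))
    stop("read_run_config: input file(s) not found")
  structure(cfg, class = "run_config")
}

#' Serialize a fitted PLS model to JSON
#'
#' Matrices are written row-major with named fields so the layout is
#' language-agnostic.
#'
#' @param model a `pls_model`.
#' @param path output file.
#' @return `invisible(path)`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(
    n_components = model$n_components,
    weights = as.data.frame(model$weights),
    x_loadings = as.data.frame(model$x_loadings),
    y_loadings = model$y_loadings,
    regression_vector = model$regression_vector,
    centering_offsets = model$centering_offsets,
    ssy_per_component = model$ssy_per_component,
    ssx_per_component = model$ssx_per_component)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
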