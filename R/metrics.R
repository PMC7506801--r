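#' Cross-validation specification
#'
#' @param n_folds number of folds (2..n); ignored if `loo = TRUE`.
#' @param max_components largest component count on the RMSEP curve.
#' @param selection_rule `"one_se"` (default): smallest component count
#'   whose RMSEP is within one standard error of the curve minimum;
#'   `"abs_minimum"`: the curve minimum itself (smallest index on ties).
#' @param seed seed for fold shuffling.
#' @param loo leave-one-out instead of k-fold.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 10L, max_components = 15L,
                    selection_rule = c("one_se", "abs_minimum"),
                    seed = 1L, loo = FALSE) {
  selection_rule <- match.arg(selection_rule)
  if (!loo && n_folds < 2L) stop("cv_spec: n_folds must be >= 2")
  if (max_components < 1L) stop("cv_spec: max_components must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 max_components = as.integer(max_components),
                 selection_rule = selection_rule,
                 seed = as.integer(seed), loo = loo),
            class = "cv_spec")
}

# seeded fold assignment, balanced sizes
make_folds <- function(n, spec) {
  k <- if (spec$loo) n else min(spec$n_folds, n)
  set.seed(spec$seed)
  sample(rep_len(seq_len(k), n))
}

#' Cross-validated RMSEP curve and component selection
#'
#' Fits the model on each training fold once at the maximal component
#' count and collects out-of-fold predictions for every component count
#' from one NIPALS pass. RMSEP per component count is the pooled
#' root-mean-square out-of-fold error; its standard error is the
#' standard deviation of per-fold RMSEP values divided by `sqrt(folds)`.
#' Two selections are reported: the absolute minimum of the curve and
#' the one-standard-error choice (smallest count within one SE of the
#' minimum).
#'
#' @param data a [spectra_dataset()].
#' @param spec a [cv_spec()].
#' @param folds optional precomputed fold assignment (integer vector of
#'   length `n`), e.g. to share folds across methods.
#' @return An object of class `cv_result` with `rmsep_by_components`,
#'   `rmsep_se_by_components`, `selected_components`,
#'   `abs_minimum_components`, `predictions` (n x max_components matrix
#'   of out-of-fold predictions) and `folds`.
#' @export
cross_validate <- function(data, spec = cv_spec(), folds = NULL) {
  data <- as_spectra_dataset(data)
  n <- nrow(data$X); m <- ncol(data$X)
  if (is.null(folds)) folds <- make_folds(n, spec)
  k <- max(folds)
  min_train <- n - max(tabulate(folds, k))   # smallest training split
  lmax <- min(spec$max_components, min_train - 1L, m)
  if (lmax < 1L)
    stop("cross_validate: folds too small for even one component")

  pred <- matrix(NA_real_, n, lmax)
  fold_rmsep <- matrix(NA_real_, k, lmax)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- suppressWarnings(
      fit_plsr(spectra_dataset(data$X[train, , drop = FALSE], data$y[train]),
               min(lmax, length(train) - 1L)))
    p <- predict_components(fit, data$X[test, , drop = FALSE])
    if (ncol(p) < lmax)  # deficient fit: pad by repeating last column
      p <- cbind(p, p[, rep(ncol(p), lmax - ncol(p)), drop = FALSE])
    pred[test, ] <- p
    fold_rmsep[f, ] <- sqrt(colMeans((data$y[test] - p)^2))
  }
  rmsep <- sqrt(colMeans((data$y - pred)^2))
  rmsep_se <- apply(fold_rmsep, 2L, stats::sd) / sqrt(k)

  abs_min <- which.min(rmsep)          # first index on ties
  thresh <- rmsep[abs_min] + rmsep_se[abs_min]
  one_se <- which(rmsep <= thresh)[1L]
  selected <- if (spec$selection_rule == "one_se") one_se else abs_min

  structure(list(rmsep_by_components = rmsep,
                 rmsep_se_by_components = rmsep_se,
                 selected_components = as.integer(selected),
                 abs_minimum_components = as.integer(abs_min),
                 selection_rule = spec$selection_rule,
                 predictions = pred, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result: RMSEP over 1..", length(x$rmsep_by_components),
      " components\n", sep = "")
  cat("  abs minimum at ", x$abs_minimum_components, " (RMSEP ",
      format(x$rmsep_by_components[x$abs_minimum_components], digits = 5),
      "); selection (", x$selection_rule, ") = ",
      x$selected_components, "\n", sep = "")
  invisible(x)
}

#' Evaluation statistics for calibration predictions
#'
#' Computes the four summary statistics used to benchmark calibration
#' models: `rmse = sqrt(mean(e^2))`; `r2`, the squared Pearson
#' correlation between reference and predicted values (bounded in
#' `[0, 1]` by construction); `rpd = sd(reference) / rmse`; and `se`,
#' the bias-corrected standard deviation of the residuals
#' (`sqrt(sum((e - mean(e))^2) / (n - 1))`).
#'
#' @param reference observed response values.
#' @param predicted model predictions, same length.
#' @param n_components optional component count to carry in the result.
#' @return An object of class `evaluation_metrics`:
#'   list(rmse, r2, rpd, se, n_components).
#' @export
evaluate <- function(reference, predicted, n_components = NA_integer_) {
  if (length(reference) != length(predicted))
    stop("evaluate: reference and predicted lengths differ")
  if (length(reference) < 2L) stop("evaluate: need at least 2 values")
  e <- reference - predicted
  rmse <- sqrt(mean(e^2))
  sd_ref <- stats::sd(reference)
  if (sd_ref == 0)
    stop("evaluate: zero variance in reference; r2 and rpd undefined")
  r2 <- if (stats::sd(predicted) == 0) 0 else
    stats::cor(reference, predicted)^2
  rpd <- if (rmse > 0) sd_ref / rmse else Inf
  se <- stats::sd(e)
  structure(list(rmse = rmse, r2 = r2, rpd = rpd, se = se,
                 n_components = as.integer(n_components)),
            class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("evaluation_metrics: RMSE %.4g | R2 %.4g | RPD %.4g | SE %.4g",
              x$rmse, x$r2, x$rpd, x$se))
  if (!is.na(x$n_components)) cat(" |", x$n_components, "components")
  cat("\n")
  invisible(x)
}

#' Write an RMSEP curve as TSV
#'
#' @param cv a `cv_result`.
#' @param path output file.
#' @return The written data frame, invisibly.
#' @export
write_rmsep_tsv <- function(cv, path) {
  df <- data.frame(components = seq_along(cv$rmsep_by_components),
                   rmsep = cv$rmsep_by_components,
                   se = cv$rmsep_se_by_components)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
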