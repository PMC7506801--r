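#' Diagonal input-scaling matrix
#'
#' Non-negative per-wavelength factors `lambda_j` applied as
#' `X_scaled = X %*% diag(lambda)`. Stored as the factor vector with a
#' provenance tag.
#'
#' @param factors numeric vector of non-negative, finite factors.
#' @param provenance one of `"vip_total"`, `"mcuve_reliability"`,
#'   `"identity"`, `"autoscale"`, `"vip_classical"`.
#' @return An object of class `scaling_matrix`.
#' @export
scaling_matrix <- function(factors,
                           provenance = c("identity", "vip_total",
                                          "mcuve_reliability", "autoscale",
                                          "vip_classical")) {
  provenance <- match.arg(provenance)
  factors <- as.numeric(factors)
  if (any(!is.finite(factors)) || any(factors < 0))
    stop("scaling_matrix: factors must be finite and >= 0")
  structure(list(factors = factors, provenance = provenance),
            class = "scaling_matrix")
}

#' Auto-scale a dataset
#'
#' Standardizes every predictor column to zero mean and unit standard
#' deviation (the conventional pre-processing for PLSR when no
#' informative scaling is available). The response is left untouched.
#'
#' @param data a [spectra_dataset()].
#' @return A list with `data` (scaled `spectra_dataset`), `offsets`
#'   (column means) and `divisors` (column sds).
#' @export
auto_scale <- function(data) {
  data <- as_spectra_dataset(data)
  mu <- colMeans(data$X)
  s <- apply(data$X, 2L, stats::sd)
  zero <- which(s == 0)
  if (length(zero))
    stop("auto_scale: zero-variance column(s): ",
         paste(zero, collapse = ", "))
  Xs <- sweep(sweep(data$X, 2L, mu, "-"), 2L, s, "/")
  list(data = spectra_dataset(Xs, data$y, data$wavelengths),
       offsets = mu, divisors = s)
}

#' Apply a diagonal scaling to a dataset
#'
#' @param data a [spectra_dataset()].
#' @param omega a [scaling_matrix()] (or bare numeric factor vector).
#' @return The scaled `spectra_dataset`; wavelength labels preserved.
#' @export
apply_scaling <- function(data, omega) {
  data <- as_spectra_dataset(data)
  if (!inherits(omega, "scaling_matrix")) omega <- scaling_matrix(omega)
  lambda <- omega$factors
  if (length(lambda) != ncol(data$X))
    stop("apply_scaling: ", length(lambda), " factors for ",
         ncol(data$X), " columns")
  spectra_dataset(sweep(data$X, 2L, lambda, "*"), data$y, data$wavelengths)
}

#' The three-step mod-VIP-MCUVE selection and scaling pipeline
#'
#' Robust wavelength selection by input scaling:
#' \enumerate{
#'   \item Fit an OPLS model on the raw data and compute the total
#'     OPLS-VIP score; rescale `X` by it (`X1 = X diag(VIP_total)`).
#'   \item Run MCUVE on the rescaled matrix (artificial noise columns
#'     appended after scaling, so they stay uninformative) and compute
#'     the robust tolerance-interval cut-off
#'     `median(c_artif) + k MAD(c_artif)`.
#'   \item Rescale by the absolute reliabilities
#'     (`X2 = X1 diag(|c_j|)`, cumulative by default) and fit the final
#'     PLSR with a cross-validation-selected component count.
#' }
#' Reliabilities enter as `|c_j|` because scaling factors must be
#' non-negative; the signed robust classification (`c_j > cutoff`) is
#' kept in the selection report.
#'
#' @param data a [spectra_dataset()].
#' @param opls_spec list with `n_predictive` and `n_orthogonal` for
#'   step 1; `n_predictive = NULL` (default) uses the cross-validated
#'   component count on the raw data.
#' @param mcuve_params an [mcuve_params()].
#' @param tolerance_params a [tolerance_k()] result; default
#'   `gamma = 0.95`, `alpha = 0.05` at the MCUVE resample count.
#' @param cv_spec a [cv_spec()] shared by all component selections.
#' @param step3_from one of `"cumulative"` (default: rescale the step-1
#'   output) or `"raw"` (rescale the raw matrix by `|c_j|` alone).
#' @return An object of class `pipeline_result`; see Details.
#' @details The result carries `step1_scores`, `step1_scaled`,
#'   `step2_result`, `step3_scaled`, `final_model`, `final_cv`,
#'   `final_metrics` (on the pooled cross-validated predictions),
#'   `fit_metrics` (refit on all samples at the selected component
#'   count) and a per-wavelength `selection_report` data frame.
#' @export
mod_vip_mcuve <- function(data,
                          opls_spec = list(n_predictive = NULL,
                                           n_orthogonal = 1L),
                          mcuve_params = wavesel::mcuve_params(),
                          tolerance_params = NULL,
                          cv_spec = wavesel::cv_spec(),
                          step3_from = c("cumulative", "raw")) {
  data <- as_spectra_dataset(data)
  step3_from <- match.arg(step3_from)
  n <- nrow(data$X); m <- ncol(data$X)

  # Step 1: OPLS-VIP total score as initial scaling
  n_pred <- opls_spec$n_predictive
  if (is.null(n_pred)) {
    cv0 <- cross_validate(data, cv_spec)
    n_pred <- cv0$selected_components
  }
  n_orth <- if (is.null(opls_spec$n_orthogonal)) 1L else
    as.integer(opls_spec$n_orthogonal)
  n_orth <- min(n_orth, max(0L, min(n - 1L, m) - n_pred))
  opls <- fit_opls(data, n_pred, n_orth)
  vip_total <- opls_vip(opls, "total")
  omega1 <- scaling_matrix(as.numeric(vip_total), "vip_total")
  if (all(omega1$factors == 0))
    stop("mod_vip_mcuve [step 1]: all VIP-total factors are zero")
  step1 <- apply_scaling(data, omega1)

  # Step 2: modified MCUVE with robust cut-off on the scaled matrix
  aug <- augment_noise(step1, mcuve_params)
  step2 <- tryCatch(
    mc_reliability(aug, mcuve_params, cv_spec),
    error = function(e) stop("mod_vip_mcuve [step 2]: ", conditionMessage(e)))
  if (is.null(tolerance_params))
    tolerance_params <- tolerance_k(0.95, 0.05, mcuve_params$n_resamples)
  step2 <- robust_cutoff(step2, tolerance_params)

  # Step 3: rescale by |c_j| and refit
  cj <- step2$reliability
  lambda2 <- abs(cj)
  lambda2[!is.finite(lambda2)] <- max(lambda2[is.finite(lambda2)], 1)
  if (all(lambda2 == 0))
    stop("mod_vip_mcuve [step 3]: all reliability factors are zero; ",
         "review the cut-off parameters")
  omega2 <- scaling_matrix(lambda2, "mcuve_reliability")
  base <- if (step3_from == "cumulative") step1 else data
  step3 <- apply_scaling(base, omega2)

  final_cv <- cross_validate(step3, cv_spec)
  final_model <- fit_plsr(step3, final_cv$selected_components)
  final_metrics <- evaluate(step3$y,
                            final_cv$predictions[, final_cv$selected_components],
                            final_cv$selected_components)
  fit_metrics <- evaluate(step3$y, predict(final_model, step3),
                          final_cv$selected_components)

  final_lambda <- if (step3_from == "cumulative")
    omega1$factors * lambda2 else lambda2
  report <- data.frame(
    wavelength = if (is.null(data$wavelengths)) seq_len(m) else
      as.character(data$wavelengths),
    vip_total = as.numeric(vip_total),
    reliability = cj,
    final_factor = final_lambda,
    above_cutoff = step2$selected_mask)

  structure(list(step1_scores = vip_total, step1_scaled = step1,
                 step2_result = step2, step3_scaled = step3,
                 final_model = final_model, final_cv = final_cv,
                 final_metrics = final_metrics, fit_metrics = fit_metrics,
                 selection_report = report,
                 opls_model = opls,
                 cutoff_value = step2$cutoff_value,
                 step3_from = step3_from),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("mod-VIP-MCUVE pipeline result\n")
  cat("  robust cutoff: ", format(x$cutoff_value, digits = 5), "; ",
      sum(x$selection_report$above_cutoff), " of ",
      nrow(x$selection_report), " variables above it\n", sep = "")
  cat("  final PLSR: ", x$final_model$n_components, " components; CV ",
      sep = "")
  print(x$final_metrics)
  invisible(x)
}

#' Fit one comparator method under a common CV protocol
#'
#' The four calibration strategies benchmarked against each other:
#' \describe{
#'   \item{plsr}{auto-scaled classical PLSR.}
#'   \item{vip}{PLSR on `X` rescaled by classical VIP scores (from a
#'     PLSR fit with CV-selected components).}
#'   \item{mcuve}{PLSR on `X` rescaled by `|c_j|` with columns below
#'     the classical max-of-noise cut-off zeroed (falling back to pure
#'     `|c_j|` scaling if nothing survives).}
#'   \item{mod-vip-mcuve}{the full [mod_vip_mcuve()] pipeline.}
#' }
#' All methods use the same fold assignment when `folds` is supplied.
#'
#' @param data a [spectra_dataset()].
#' @param method method identifier.
#' @param cv_spec a [cv_spec()].
#' @param mcuve_params an [mcuve_params()] (used by mcuve and the
#'   pipeline).
#' @param folds optional shared fold assignment.
#' @param hard_selection if `TRUE`, the vip and mcuve comparators drop
#'   (zero out) variables below their cut-offs instead of scaling only.
#' @return list(method, metrics (an `evaluation_metrics`), cv
#'   (a `cv_result`), n_components).
#' @export
run_comparator <- function(data, method = c("plsr", "vip", "mcuve",
                                            "mod-vip-mcuve"),
                           cv_spec = wavesel::cv_spec(),
                           mcuve_params = wavesel::mcuve_params(),
                           folds = NULL, hard_selection = FALSE) {
  method <- match.arg(method)
  data <- as_spectra_dataset(data)
  if (is.null(folds)) folds <- make_folds(nrow(data$X), cv_spec)

  finish <- function(ds) {
    cv <- cross_validate(ds, cv_spec, folds = folds)
    k <- cv$selected_components
    refit <- fit_plsr(ds, k)
    list(method = method,
         metrics = evaluate(ds$y, cv$predictions[, k], k),
         fit_metrics = evaluate(ds$y, predict(refit, ds), k),
         cv = cv, n_components = k)
  }

  if (method == "plsr") return(finish(auto_scale(data)$data))

  if (method == "vip") {
    cv0 <- cross_validate(data, cv_spec, folds = folds)
    fit <- fit_plsr(data, cv0$selected_components)
    v <- as.numeric(classical_vip(fit))
    if (hard_selection) v[v <= 1] <- 0
    if (all(v == 0)) v <- as.numeric(classical_vip(fit))
    return(finish(apply_scaling(data, scaling_matrix(v, "vip_classical"))))
  }

  if (method == "mcuve") {
    aug <- augment_noise(data, mcuve_params)
    res <- classical_cutoff(mc_reliability(aug, mcuve_params, cv_spec))
    lambda <- abs(res$reliability)
    lambda[!is.finite(lambda)] <- max(lambda[is.finite(lambda)], 1)
    kept <- lambda * as.numeric(res$selected_mask)
    if (any(kept > 0)) lambda <- kept   # classical elimination of the rest
    return(finish(apply_scaling(data,
                                scaling_matrix(lambda, "mcuve_reliability"))))
  }

  pr <- mod_vip_mcuve(data, mcuve_params = mcuve_params, cv_spec = cv_spec)
  list(method = method, metrics = pr$final_metrics,
       fit_metrics = pr$fit_metrics, cv = pr$final_cv,
       n_components = pr$final_model$n_components, pipeline = pr)
}
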