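#' Parameters for Monte Carlo uninformative variable elimination
#'
#' @param n_resamples number of random subsamples `r` (>= 2; default 500).
#' @param subsample_fraction fraction of samples per resample (default 0.8).
#' @param n_components PLS components per sub-model; `NULL` (default)
#'   selects by cross-validation on the full data once, then holds the
#'   count fixed across resamples.
#' @param noise_column_count artificial noise columns appended; `NULL`
#'   means one per real variable.
#' @param noise_amplitude scale of the uniform(0,1) artificial values
#'   (default `1e-10`, the classical UVE convention: reliability is
#'   scale-free, so near-zero noise columns calibrate the cut-off
#'   without perturbing the fit).
#' @param seed RNG seed for resampling and noise generation.
#' @return An object of class `mcuve_params`.
#' @export
mcuve_params <- function(n_resamples = 500L, subsample_fraction = 0.8,
                         n_components = NULL, noise_column_count = NULL,
                         noise_amplitude = 1e-10, seed = 1L) {
  if (n_resamples < 2L) stop("mcuve_params: n_resamples must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction >= 1)
    stop("mcuve_params: subsample_fraction must lie in (0, 1)")
  if (noise_amplitude <= 0) stop("mcuve_params: noise_amplitude must be > 0")
  structure(list(n_resamples = as.integer(n_resamples),
                 subsample_fraction = subsample_fraction,
                 n_components = n_components,
                 noise_column_count = noise_column_count,
                 noise_amplitude = noise_amplitude,
                 seed = as.integer(seed)),
            class = "mcuve_params")
}

#' Append artificial uninformative noise variables
#'
#' Adds `noise_column_count` columns of uniform(0,1) values scaled by
#' `noise_amplitude` to the predictor matrix. Their reliability
#' coefficients calibrate the MCUVE cut-off.
#'
#' @param data a [spectra_dataset()].
#' @param params an [mcuve_params()] object.
#' @return A list with `data` (augmented `spectra_dataset`),
#'   `real_index` and `noise_index`.
#' @export
augment_noise <- function(data, params) {
  data <- as_spectra_dataset(data)
  m <- ncol(data$X)
  k <- params$noise_column_count
  if (is.null(k)) k <- m
  k <- as.integer(k)
  set.seed(params$seed)
  N <- matrix(stats::runif(nrow(data$X) * k), nrow(data$X), k) *
    params$noise_amplitude
  Xa <- cbind(data$X, N)
  wl <- data$wavelengths
  if (!is.null(wl)) wl <- c(as.character(wl), paste0("noise_", seq_len(k)))
  list(data = spectra_dataset(Xa, data$y, wl),
       real_index = seq_len(m),
       noise_index = m + seq_len(k))
}

# reliability c_j = mean(b_j) / sd(b_j), sd with r - 1 denominator;
# columns with zero spread get +/- Inf (maximally reliable) or NaN when
# every coefficient is exactly zero.
compute_reliability <- function(coefficient_matrix) {
  b_bar <- colMeans(coefficient_matrix)
  s <- apply(coefficient_matrix, 2L, stats::sd)
  c_j <- b_bar / s
  zero_spread <- s == 0
  if (any(zero_spread)) {
    c_j[zero_spread & b_bar > 0] <- Inf
    c_j[zero_spread & b_bar < 0] <- -Inf
    c_j[zero_spread & b_bar == 0] <- NaN
  }
  list(reliability = c_j, mean = b_bar, sd = s)
}

#' MCUVE reliability coefficients
#'
#' Fits `r` PLS sub-models on seeded random subsamples of a
#' noise-augmented dataset and computes, for every column `j`, the
#' reliability `c_j = mean(b_j) / sd(b_j)` of its regression
#' coefficient across sub-models (standard deviation with `r - 1`
#' denominator). Stable coefficients give large `|c_j|`; the appended
#' artificial columns give the null reference. Columns whose
#' coefficient never varies are reported as infinitely reliable with a
#' warning; all-zero columns give `NaN`.
#'
#' @param augmented result of [augment_noise()] (or a plain
#'   `spectra_dataset`, in which case every column is treated as real).
#' @param params an [mcuve_params()] object. When
#'   `params$n_components` is `NULL` the sub-model component count is
#'   chosen once by cross-validation on the full augmented data.
#' @param cv_spec a [cv_spec()] used only for that one-off component
#'   selection.
#' @return An object of class `mcuve_result` with per-variable
#'   reliabilities, the `r x (m + noise)` coefficient record, and slots
#'   for a cut-off to be attached by [classical_cutoff()] or
#'   [robust_cutoff()].
#' @export
mc_reliability <- function(augmented, params, cv_spec = NULL) {
  if (inherits(augmented, "spectra_dataset"))
    augmented <- list(data = augmented,
                      real_index = seq_len(ncol(augmented$X)),
                      noise_index = integer(0))
  data <- augmented$data
  n <- nrow(data$X); m_aug <- ncol(data$X)
  r <- params$n_resamples
  n_sub <- max(2L, floor(params$subsample_fraction * n))

  ncomp <- params$n_components
  if (is.null(ncomp)) {
    if (is.null(cv_spec)) cv_spec <- cv_spec(seed = params$seed)
    cv <- cross_validate(data, cv_spec)
    ncomp <- cv$selected_components
  }
  ncomp <- as.integer(ncomp)
  if (n_sub < ncomp + 1L)
    stop("mc_reliability: subsample size ", n_sub,
         " too small for ", ncomp, " components")

  set.seed(params$seed + 1L)
  B <- matrix(0, r, m_aug)
  for (i in seq_len(r)) {
    idx <- sample.int(n, n_sub)
    sub <- spectra_dataset(data$X[idx, , drop = FALSE], data$y[idx])
    fit <- fit_plsr(sub, ncomp)
    B[i, ] <- fit$regression_vector
  }
  rel <- compute_reliability(B)
  if (any(!is.finite(rel$reliability)))
    warning("mc_reliability: ", sum(!is.finite(rel$reliability)),
            " column(s) with zero coefficient spread reported as ",
            "infinitely reliable / NaN")
  structure(list(
    reliability = rel$reliability[augmented$real_index],
    reliability_artificial = rel$reliability[augmented$noise_index],
    coefficient_matrix = B,
    mean_coefficients = rel$mean,
    coefficient_sd = rel$sd,
    real_index = augmented$real_index,
    noise_index = augmented$noise_index,
    n_components = ncomp,
    n_resamples = r,
    cutoff_value = NA_real_, cutoff_kind = NA_character_,
    selected_mask = NULL),
    class = "mcuve_result")
}

#' Classical MCUVE cut-off
#'
#' The maximum absolute reliability among the artificial noise
#' variables; real variables with `|c_j|` below it are flagged for
#' elimination.
#'
#' @param result an `mcuve_result` with at least one artificial column.
#' @return The `mcuve_result` updated with `cutoff_value`,
#'   `cutoff_kind = "classical"` and `selected_mask`
#'   (`|c_j| >= cutoff`).
#' @export
classical_cutoff <- function(result) {
  ca <- result$reliability_artificial
  if (length(ca) == 0L)
    stop("classical_cutoff: no artificial noise variables in result")
  cutoff <- max(abs(ca[is.finite(ca)]))
  result$cutoff_value <- cutoff
  result$cutoff_kind <- "classical"
  cj <- result$reliability
  result$selected_mask <- !is.na(cj) & (abs(cj) >= cutoff | is.infinite(cj))
  result
}

#' One-sided normal tolerance-interval k factor
#'
#' Approximate factor `k` such that `mean + k sd` of `r` observations
#' covers at least a proportion `gamma` of a normal population with
#' confidence `1 - alpha`:
#' `k = (z_gamma + sqrt(z_gamma^2 - a b)) / a` with
#' `a = 1 - z_alpha^2 / (2 (r - 1))` and `b = z_gamma^2 - z_alpha^2 / r`.
#' As `r` grows, `k` tends to `z_gamma`.
#'
#' @param gamma desired population proportion (0 < gamma < 1).
#' @param alpha error level (0 < alpha < 1).
#' @param r number of observations (>= 3).
#' @return An object of class `tolerance_params` with `k_factor` and the
#'   intermediate constants `a_const`, `b_const`.
#' @export
tolerance_k <- function(gamma = 0.95, alpha = 0.05, r = 500L) {
  if (gamma <= 0 || gamma >= 1) stop("tolerance_k: gamma must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("tolerance_k: alpha must be in (0, 1)")
  if (r < 3L) stop("tolerance_k: r must be >= 3")
  zg <- stats::qnorm(gamma)
  za <- stats::qnorm(1 - alpha)
  a <- 1 - za^2 / (2 * (r - 1))
  b <- zg^2 - za^2 / r
  if (a <= 0)
    stop("tolerance_k: constant a = ", format(a),
         " <= 0; r too small for this alpha")
  disc <- zg^2 - a * b
  if (disc < 0)
    stop("tolerance_k: negative discriminant z_gamma^2 - a*b = ",
         format(disc), "; invalid (gamma, alpha, r) combination")
  structure(list(gamma = gamma, alpha = alpha, r = as.integer(r),
                 k_factor = (zg + sqrt(disc)) / a,
                 a_const = a, b_const = b),
            class = "tolerance_params")
}

#' Robust tolerance-interval cut-off for MCUVE
#'
#' Replaces the classical maximum-of-noise rule with the robust
#' one-sided tolerance bound
#' `cutoff = median(c_artif) + k * MAD(c_artif)`,
#' where `k` comes from [tolerance_k()]. By default the MAD carries the
#' normal-consistency factor 1.4826 so that median + k MAD mimics
#' mean + k sd under Gaussian noise; set `mad_constant = 1` for the raw
#' MAD. Real variables are classified on the signed reliability:
#' `c_j > cutoff` marks the most relevant variables.
#'
#' @param result an `mcuve_result` with >= 3 artificial reliabilities.
#' @param tol a `tolerance_params` object from [tolerance_k()].
#' @param mad_constant consistency factor for [stats::mad()]
#'   (default 1.4826).
#' @return The `mcuve_result` updated with `cutoff_value`,
#'   `cutoff_kind = "robust"` and `selected_mask` (`c_j > cutoff`).
#' @export
robust_cutoff <- function(result, tol = tolerance_k(),
                          mad_constant = 1.4826) {
  ca <- result$reliability_artificial
  ca <- ca[is.finite(ca)]
  if (length(ca) < 3L)
    stop("robust_cutoff: need at least 3 finite artificial reliabilities")
  cutoff <- stats::median(ca) +
    tol$k_factor * stats::mad(ca, constant = mad_constant)
  result$cutoff_value <- cutoff
  result$cutoff_kind <- "robust"
  cj <- result$reliability
  result$selected_mask <- !is.na(cj) & (cj > cutoff | is.infinite(cj))
  result
}

#' @export
print.mcuve_result <- function(x, ...) {
  cat("mcuve_result: ", length(x$reliability), " real + ",
      length(x$reliability_artificial), " artificial variables, r = ",
      x$n_resamples, " resamples, ", x$n_components,
      " components per sub-model\n", sep = "")
  if (!is.na(x$cutoff_value))
    cat("  ", x$cutoff_kind, " cutoff = ", format(x$cutoff_value, digits = 5),
        "; ", sum(x$selected_mask), " variables selected\n", sep = "")
  invisible(x)
}

#' Write an MCUVE reliability table as TSV
#'
#' @param result an `mcuve_result`.
#' @param path output file.
#' @param wavelengths optional labels for the real variables.
#' @return The written data frame, invisibly.
#' @export
write_mcuve_tsv <- function(result, path, wavelengths = NULL) {
  if (is.null(wavelengths)) wavelengths <- seq_along(result$reliability)
  df <- data.frame(
    variable = c(as.character(wavelengths),
                 paste0("noise_", seq_along(result$reliability_artificial))),
    reliability = c(result$reliability, result$reliability_artificial),
    artificial = rep(c(FALSE, TRUE),
                     c(length(result$reliability),
                       length(result$reliability_artificial))),
    cutoff = result$cutoff_value,
    selected = c(if (is.null(result$selected_mask))
      rep(NA, length(result$reliability)) else result$selected_mask,
      rep(NA, length(result$reliability_artificial))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
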