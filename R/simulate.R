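#' Configuration for the synthetic calibration-data generator
#'
#' Describes one scenario of the Monte Carlo study: `n` samples, `m`
#' total predictors of which a fraction `iv_fraction` are "important"
#' (carry a nonzero regression coefficient). The remaining predictors
#' split into further observable-but-unimportant covariates and
#' `floor((m - n_iv) / 2)` artificial-noise covariates drawn on a
#' shifted support. All predictors receive additive Gaussian noise and
#' the response is a linear combination of the important columns plus
#' Gaussian error.
#'
#' @param n sample count (>= 2).
#' @param m total predictor count (>= 2).
#' @param iv_fraction proportion of important variables, in (0, 1).
#' @param lo_bounds_obs support of observable covariates (default
#'   `c(1, 10)`).
#' @param lo_bounds_noise support of artificial-noise covariates
#'   (default `c(5, 20)`).
#' @param coef_bounds support of the uniform regression coefficients on
#'   the important subset (default `c(0, 7)`).
#' @param noise_sd_x standard deviation of additive predictor noise
#'   (default 1).
#' @param noise_sd_y standard deviation of the response error
#'   (default 1).
#' @param seed RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n, m, iv_fraction,
                              lo_bounds_obs = c(1, 10),
                              lo_bounds_noise = c(5, 20),
                              coef_bounds = c(0, 7),
                              noise_sd_x = 1, noise_sd_y = 1,
                              seed = 1L) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 2L) stop("simulation_config: n must be >= 2")
  if (m < 2L) stop("simulation_config: m must be >= 2")
  if (iv_fraction <= 0 || iv_fraction >= 1)
    stop("simulation_config: iv_fraction must lie in (0, 1)")
  for (b in list(lo_bounds_obs, lo_bounds_noise, coef_bounds))
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] >= b[2L])
      stop("simulation_config: bounds must be finite with lower < upper")
  if (noise_sd_x <= 0 || noise_sd_y <= 0)
    stop("simulation_config: noise sds must be > 0")
  structure(list(n = n, m = m, iv_fraction = iv_fraction,
                 lo_bounds_obs = lo_bounds_obs,
                 lo_bounds_noise = lo_bounds_noise,
                 coef_bounds = coef_bounds,
                 noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# nearest-integer rounding with ties away from zero (round half up for
# the positive counts used here); base round() rounds half to even.
round_half_up <- function(x) floor(x + 0.5)

#' Generate one synthetic calibration dataset
#'
#' Draws `m_o` observable covariates uniform on `lo_bounds_obs` and
#' `m_e = floor((m - n_iv) / 2)` artificial-noise covariates uniform on
#' `lo_bounds_noise` (`n_iv = round(iv_fraction * m)`, half up), adds
#' elementwise Gaussian noise (`noise_sd_x`) to every predictor column,
#' samples coefficients uniform on `coef_bounds` for `n_iv` important
#' columns chosen at random among the observable ones, and sets
#' `y = X[, iv] %*% b + e0` with Gaussian response error. The noisy
#' predictor matrix itself (noise included) enters the response, i.e.
#' the observed covariates are the ones that generate `y`.
#'
#' @param config a [simulation_config()].
#' @return An object of class `simulated_dataset`: a
#'   [spectra_dataset()] plus `important_index_set`, `noise_index_set`
#'   and `true_coefficients` (named by important column index).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n; m <- config$m
  n_iv <- as.integer(round_half_up(config$iv_fraction * m))
  if (n_iv == 0L || n_iv >= m)
    stop("generate_dataset: invalid configuration, n_iv = ", n_iv,
         " after rounding (must satisfy 0 < n_iv < m)")
  m_e <- as.integer(floor((m - n_iv) / 2))
  m_o <- m - m_e

  set.seed(config$seed)
  X <- matrix(0, n, m)
  obs_cols <- seq_len(m_o)
  noise_cols <- if (m_e > 0L) m_o + seq_len(m_e) else integer(0)
  X[, obs_cols] <- stats::runif(n * m_o, config$lo_bounds_obs[1L],
                                config$lo_bounds_obs[2L])
  if (m_e > 0L)
    X[, noise_cols] <- stats::runif(n * m_e, config$lo_bounds_noise[1L],
                                    config$lo_bounds_noise[2L])
  X <- X + matrix(stats::rnorm(n * m, 0, config$noise_sd_x), n, m)

  iv <- sort(sample(obs_cols, n_iv))
  b <- stats::runif(n_iv, config$coef_bounds[1L], config$coef_bounds[2L])
  y <- drop(X[, iv, drop = FALSE] %*% b) +
    stats::rnorm(n, 0, config$noise_sd_y)

  ds <- spectra_dataset(X, y)
  ds$important_index_set <- iv
  ds$noise_index_set <- noise_cols
  ds$true_coefficients <- stats::setNames(b, iv)
  ds$config <- config
  class(ds) <- c("simulated_dataset", class(ds))
  ds
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset: ", nrow(x$X), " x ", ncol(x$X), "; ",
      length(x$important_index_set), " important, ",
      length(x$noise_index_set), " artificial-noise columns\n", sep = "")
  invisible(x)
}
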