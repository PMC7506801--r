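#' Fit a PLSR model by NIPALS
#'
#' Single-response partial least squares regression. Columns of `X` and
#' the response are mean-centered (no variance scaling; scaling is an
#' explicit, separate step in this package), then components are
#' extracted by the NIPALS recursion with deflation of `X` and `y`.
#' For a single response the inner loop is closed form: the weight
#' vector is `w = X'y / ||X'y||` at every component.
#'
#' Per component `g` the model records the unit-norm weight `w_g`, the
#' score `v_g = X w_g`, the loading `p_g = X'v_g / v_g'v_g`, the
#' response loading `q_g = y'v_g / v_g'v_g`, and the explained sums of
#' squares `SSX_g = (v_g'v_g)(p_g'p_g)` and `SSY_g = q_g^2 (v_g'v_g)`.
#' The regression vector is the standard `b = W (P'W)^-1 q`, so that
#' fitted values are `Xc b + mean(y)`.
#'
#' @param data a [spectra_dataset()].
#' @param n_components number of latent components, between 1 and
#'   `min(n - 1, m)`.
#' @param on_deficient what to do when deflation exhausts `X` before
#'   `n_components` components are available: `"warn"` (default) stops
#'   extraction with a warning, `"error"` raises a degenerate-component
#'   error naming the component index.
#' @return An object of class `pls_model`.
#' @export
fit_plsr <- function(data, n_components, on_deficient = c("warn", "error")) {
  data <- as_spectra_dataset(data)
  on_deficient <- match.arg(on_deficient)
  X <- data$X
  y <- data$y
  n <- nrow(X); m <- ncol(X)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, m))
    stop("fit_plsr: n_components must lie in [1, min(n-1, m)] = [1, ",
         min(n - 1L, m), "], got ", n_components)

  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_means, "-")
  yc <- y - y_mean

  W <- matrix(0, m, n_components)
  V <- matrix(0, n, n_components)
  P <- matrix(0, m, n_components)
  q <- numeric(n_components)
  b_inner <- numeric(n_components)
  ssx <- numeric(n_components)
  ssy <- numeric(n_components)
  U <- matrix(0, n, n_components)   # y-residual "u" entering each component

  E <- Xc
  f <- yc
  l_used <- n_components
  vv_first <- NA_real_
  for (g in seq_len(n_components)) {
    w <- crossprod(E, f)[, 1L]
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12 * (1 + sqrt(sum(E^2)))) {
      msg <- paste0("degenerate component ", g,
                    ": weight vector has zero norm (X residual carries no ",
                    "covariance with y)")
      if (on_deficient == "error") stop("fit_plsr: ", msg)
      warning("fit_plsr: ", msg, "; returning ", g - 1L, " components")
      l_used <- g - 1L
      break
    }
    w <- w / wn
    v <- E %*% w
    vv <- sum(v^2)
    # scores collapsing relative to the leading component would make the
    # P'W system singular; stop extraction as for a zero-norm weight
    if (is.na(vv_first)) vv_first <- vv
    if (vv < 1e-20 * vv_first) {
      msg <- paste0("degenerate component ", g,
                    ": score sum of squares numerically zero")
      if (on_deficient == "error") stop("fit_plsr: ", msg)
      warning("fit_plsr: ", msg, "; returning ", g - 1L, " components")
      l_used <- g - 1L
      break
    }
    p <- crossprod(E, v)[, 1L] / vv
    qg <- sum(f * v) / vv
    U[, g] <- f
    W[, g] <- w
    V[, g] <- v
    P[, g] <- p
    q[g] <- qg
    b_inner[g] <- sum(f * v) / vv   # inner-relation slope, equals q for 1 y
    ssx[g] <- vv * sum(p^2)
    ssy[g] <- qg^2 * vv
    E <- E - tcrossprod(v, p)
    f <- f - qg * v
  }
  if (l_used == 0L)
    stop("fit_plsr: degenerate component 1: no usable covariance in X")
  idx <- seq_len(l_used)
  W <- W[, idx, drop = FALSE]; V <- V[, idx, drop = FALSE]
  P <- P[, idx, drop = FALSE]; U <- U[, idx, drop = FALSE]
  q <- q[idx]; b_inner <- b_inner[idx]
  ssx <- ssx[idx]; ssy <- ssy[idx]

  b <- regression_vector_standard(W, P, q)
  structure(list(
    n_components = l_used,
    weights = W, x_scores = V, x_loadings = P,
    y_loadings = q, inner_coefficients = b_inner,
    mixed_coefficients = q,            # a = b_inner * q' collapses to q (1 y)
    regression_vector = b,
    centering_offsets = list(x = x_means, y = y_mean),
    ssx_per_component = ssx, ssy_per_component = ssy,
    x_residual = E, y_residual = f,
    u_scores = U,
    wavelengths = data$wavelengths),
    class = "pls_model")
}

# b = W (P'W)^-1 q; P'W is upper triangular with unit-ish diagonal under
# NIPALS so the solve is well conditioned for moderate component counts.
regression_vector_standard <- function(W, P, q) {
  PtW <- crossprod(P, W)
  drop(W %*% solve(PtW, q))
}

# Direct regression-vector expression b = X'U (V'X X'U)^-1 V'y built from
# the y-residual scores entering each component and the centered X; kept as
# an algebraic cross-check of the standard form.
regression_vector_direct <- function(model, data) {
  Xc <- sweep(data$X, 2L, model$centering_offsets$x, "-")
  yc <- data$y - model$centering_offsets$y
  XtU <- crossprod(Xc, model$u_scores)
  M <- crossprod(model$x_scores, Xc %*% XtU)
  drop(XtU %*% solve(M, crossprod(model$x_scores, yc)))
}

#' Predict from a fitted PLSR model
#'
#' Centers `newdata` with the training column means, applies the
#' regression vector and adds back the training response mean.
#'
#' @param object a `pls_model`.
#' @param newdata matrix (or `spectra_dataset`) with the training column
#'   count; defaults to refitting the training data is not kept, so
#'   `newdata` is required.
#' @param n_components optionally truncate the model to its first
#'   `n_components` components before predicting.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  X <- if (inherits(newdata, "spectra_dataset")) newdata$X else as.matrix(newdata)
  m <- length(object$centering_offsets$x)
  if (ncol(X) != m)
    stop("predict.pls_model: newdata has ", ncol(X),
         " columns, model expects ", m)
  b <- object$regression_vector
  if (!is.null(n_components)) {
    k <- as.integer(n_components)
    if (k < 1L || k > object$n_components)
      stop("predict.pls_model: n_components out of range")
    b <- regression_vector_standard(object$weights[, 1:k, drop = FALSE],
                                    object$x_loadings[, 1:k, drop = FALSE],
                                    object$y_loadings[1:k])
  }
  Xc <- sweep(X, 2L, object$centering_offsets$x, "-")
  drop(Xc %*% b) + object$centering_offsets$y
}

# n x l matrix of predictions at 1..l components; used by cross-validation
# so one NIPALS fit serves the whole RMSEP curve.
predict_components <- function(object, X) {
  X <- if (inherits(X, "spectra_dataset")) X$X else as.matrix(X)
  Xc <- sweep(X, 2L, object$centering_offsets$x, "-")
  l <- object$n_components
  out <- matrix(0, nrow(X), l)
  for (k in seq_len(l)) {
    b <- regression_vector_standard(object$weights[, 1:k, drop = FALSE],
                                    object$x_loadings[, 1:k, drop = FALSE],
                                    object$y_loadings[1:k])
    out[, k] <- drop(Xc %*% b) + object$centering_offsets$y
  }
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model: ", x$n_components, " components over ",
      nrow(x$weights), " variables\n", sep = "")
  cat("  explained SSY per component: ",
      paste(format(x$ssy_per_component, digits = 4), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Fit an OPLS model (single response)
#'
#' Orthogonal projections to latent structures: response-orthogonal
#' variation is removed from `X` into an orthogonal block before the
#' predictive components are extracted. Each orthogonal component uses
#' the standard single-y recursion: with the current PLS weight
#' `w = X'y/||X'y||` and loading `p`, the orthogonal weight is
#' `w_o = p - (w'p / w'w) w`, normalized; `X` is deflated by the
#' resulting score/loading pair. The predictive block is then a NIPALS
#' PLSR fit ([fit_plsr()]) on the filtered matrix.
#'
#' Per-component explained sums of squares of `X` and `y` are recorded
#' for both blocks; orthogonal components explain no response variance
#' by construction (their scores are exactly uncorrelated with `y`).
#'
#' @param data a [spectra_dataset()].
#' @param n_predictive predictive components (>= 1).
#' @param n_orthogonal orthogonal components (>= 0).
#' @return An object of class `opls_model` with elements `predictive`
#'   (a `pls_model` on the filtered data), `orthogonal` (weights,
#'   scores, loadings), per-component and cumulative SSX/SSY, and the
#'   centering offsets of the raw data.
#' @export
fit_opls <- function(data, n_predictive, n_orthogonal = 0L) {
  data <- as_spectra_dataset(data)
  n_predictive <- as.integer(n_predictive)
  n_orthogonal <- as.integer(n_orthogonal)
  n <- nrow(data$X); m <- ncol(data$X)
  if (n_predictive < 1L) stop("fit_opls: n_predictive must be >= 1")
  if (n_orthogonal < 0L) stop("fit_opls: n_orthogonal must be >= 0")
  if (n_predictive + n_orthogonal > min(n - 1L, m))
    stop("fit_opls: n_predictive + n_orthogonal exceeds min(n-1, m) = ",
         min(n - 1L, m))

  x_means <- colMeans(data$X)
  y_mean <- mean(data$y)
  E <- sweep(data$X, 2L, x_means, "-")
  yc <- data$y - y_mean
  ssx_total <- sum(E^2)

  Wo <- matrix(0, m, n_orthogonal)
  To <- matrix(0, n, n_orthogonal)
  Po <- matrix(0, m, n_orthogonal)
  ssx_o <- numeric(n_orthogonal)
  for (go in seq_len(n_orthogonal)) {
    w <- crossprod(E, yc)[, 1L]
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) stop("fit_opls: degenerate component ", go,
                         ": no covariance left between X and y")
    w <- w / wn
    v <- E %*% w
    p <- crossprod(E, v)[, 1L] / sum(v^2)
    wo <- p - sum(w * p) / sum(w * w) * w
    won <- sqrt(sum(wo^2))
    if (won < 1e-12) stop("fit_opls: degenerate orthogonal component ", go,
                          ": no y-orthogonal structure left")
    wo <- wo / won
    to <- E %*% wo
    po <- crossprod(E, to)[, 1L] / sum(to^2)
    Wo[, go] <- wo; To[, go] <- to; Po[, go] <- po
    ssx_o[go] <- sum(to^2) * sum(po^2)
    E <- E - tcrossprod(to, po)
  }

  filtered <- spectra_dataset(sweep(E, 2L, -x_means, "-"), data$y,
                              data$wavelengths)
  pred <- fit_plsr(filtered, n_predictive)

  structure(list(
    predictive = pred,
    orthogonal = list(weights = Wo, scores = To, loadings = Po),
    n_predictive = pred$n_components,
    n_orthogonal = n_orthogonal,
    ssx_per_component = pred$ssx_per_component,
    ssx_per_orthogonal = ssx_o,
    ssy_per_component = pred$ssy_per_component,
    ssy_per_orthogonal = rep(0, n_orthogonal),
    ssx_cum = sum(pred$ssx_per_component) + sum(ssx_o),
    ssy_cum = sum(pred$ssy_per_component),
    ssx_total = ssx_total,
    ssy_total = sum(yc^2),
    centering_offsets = list(x = x_means, y = y_mean),
    wavelengths = data$wavelengths),
    class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("opls_model: ", x$n_predictive, " predictive + ", x$n_orthogonal,
      " orthogonal components over ", nrow(x$predictive$weights),
      " variables\n", sep = "")
  cat("  cumulative explained SSX ", format(x$ssx_cum, digits = 5),
      " of ", format(x$ssx_total, digits = 5), "; SSY ",
      format(x$ssy_cum, digits = 5), " of ",
      format(x$ssy_total, digits = 5), "\n", sep = "")
  invisible(x)
}
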