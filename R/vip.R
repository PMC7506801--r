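#' Classical VIP scores
#'
#' Variable importance in projection for a fitted PLSR model. With
#' normalized weight vectors `v_g = w_g / ||w_g||` (unit norm already
#' under NIPALS) and the per-component explained response sums of
#' squares `SSY_g`,
#' `VIP_j^2 = m * sum_g(v_gj^2 SSY_g) / sum_g SSY_g`.
#' The scores satisfy `sum_j VIP_j^2 = m`, so a score above 1 marks a
#' variable contributing more than average.
#'
#' @param model a `pls_model` from [fit_plsr()].
#' @return A `vip_scores` object: numeric scores with attributes
#'   `variant = "classical"`, `component_counts` and
#'   `effective_variable_counts`.
#' @export
classical_vip <- function(model) {
  if (!inherits(model, "pls_model")) stop("classical_vip: need a pls_model")
  ssy <- model$ssy_per_component
  tot <- sum(ssy)
  if (tot <= 0)
    stop("classical_vip: total explained SSY is zero; scores undefined")
  W <- model$weights
  m <- nrow(W)
  v2 <- W^2                      # columns already unit norm
  scores <- sqrt(m * drop(v2 %*% ssy) / tot)
  new_vip_scores(scores, "classical",
                 component_counts = c(l = model$n_components, l_o = 0L),
                 effective_variable_counts = c(m = m, m_o = 0, M = m),
                 wavelengths = model$wavelengths)
}

new_vip_scores <- function(scores, variant, component_counts,
                           effective_variable_counts, wavelengths = NULL) {
  structure(as.numeric(scores), variant = variant,
            component_counts = component_counts,
            effective_variable_counts = effective_variable_counts,
            wavelengths = wavelengths,
            class = "vip_scores")
}

#' OPLS-VIP scores (predictive, orthogonal, total)
#'
#' VIP scores for an OPLS model that weight the squared normalized
#' weights of each block by both the explained predictor variance
#' (`SSX`) and the explained response variance (`SSY`), each relative
#' to the cumulative explained sums of squares of the whole model:
#' \describe{
#'   \item{pred}{`VIP_j^2 = (m/2) (sum_g v_gj^2 SSX_g / SSX_cum +
#'     sum_g v_gj^2 SSY_g / SSY_cum)` over predictive components.}
#'   \item{ortho}{the same form over orthogonal components with factor
#'     `m_o/2` (orthogonal components explain no response variance, so
#'     the SSY term vanishes).}
#'   \item{total}{factor `M/2` over all four sums, predictive and
#'     orthogonal together.}
#' }
#' The variable counts use `m = ncol(X)` for the predictive block,
#' `m_o = ncol(X)` when orthogonal components exist (0 otherwise) and
#' `M = m + m_o`; with no orthogonal components the total score
#' therefore reduces exactly to the predictive score. Effective counts
#' derived from cumulative-SS ratios are attached as a diagnostic
#' attribute (`ratio_counts`) but do not enter the scores; scores are
#' used here as non-negative scaling factors, for which only relative
#' sizes matter.
#'
#' @param model an `opls_model` from [fit_opls()].
#' @param variant one of `"pred"`, `"ortho"`, `"total"`.
#' @return A `vip_scores` object.
#' @export
opls_vip <- function(model, variant = c("total", "pred", "ortho")) {
  if (!inherits(model, "opls_model")) stop("opls_vip: need an opls_model")
  variant <- match.arg(variant)
  if (model$ssx_cum <= 0 || model$ssy_cum <= 0)
    stop("opls_vip: cumulative explained SSX or SSY is zero; scores undefined")
  m <- nrow(model$predictive$weights)
  l_o <- model$n_orthogonal
  if (variant == "ortho" && l_o < 1L)
    stop("opls_vip: variant 'ortho' requires at least one orthogonal component")

  Wp2 <- model$predictive$weights^2
  pred_sum <- drop(Wp2 %*% model$ssx_per_component) / model$ssx_cum +
    drop(Wp2 %*% model$ssy_per_component) / model$ssy_cum
  if (l_o > 0L) {
    Wo2 <- model$orthogonal$weights^2
    ortho_sum <- drop(Wo2 %*% model$ssx_per_orthogonal) / model$ssx_cum +
      drop(Wo2 %*% model$ssy_per_orthogonal) / model$ssy_cum
  } else ortho_sum <- numeric(m)

  m_o <- if (l_o > 0L) m else 0
  M <- m + m_o
  scores2 <- switch(variant,
    pred  = (m / 2) * pred_sum,
    ortho = (m_o / 2) * ortho_sum,
    total = (M / 2) * (pred_sum + ortho_sum))

  rp <- sum(model$ssx_per_component) / model$ssx_cum +
    sum(model$ssy_per_component) / model$ssy_cum
  ro <- sum(model$ssx_per_orthogonal) / model$ssx_cum +
    sum(model$ssy_per_orthogonal) / model$ssy_cum
  ratio_counts <- c(M = m * rp, m_o = if (ro > 0) m * rp / ro else 0)

  out <- new_vip_scores(sqrt(pmax(scores2, 0)), paste0("opls_", variant),
                        component_counts = c(l = model$n_predictive, l_o = l_o),
                        effective_variable_counts = c(m = m, m_o = m_o, M = M),
                        wavelengths = model$wavelengths)
  attr(out, "ratio_counts") <- ratio_counts
  out
}

#' Three-way relevance classification from VIP scores
#'
#' The conventional reading of VIP scores: strictly above
#' `relevant_threshold` is "relevant", strictly below
#' `irrelevant_threshold` is "irrelevant", everything in between
#' (boundaries included) is "intermediate".
#'
#' @param scores a `vip_scores` object or numeric vector.
#' @param relevant_threshold score above which a variable is relevant
#'   (default 1).
#' @param irrelevant_threshold score below which a variable is
#'   irrelevant (default 0.5).
#' @return A list with `label` (factor with levels relevant /
#'   intermediate / irrelevant) and `counts`.
#' @export
classify_by_vip <- function(scores, relevant_threshold = 1,
                            irrelevant_threshold = 0.5) {
  if (irrelevant_threshold > relevant_threshold)
    stop("classify_by_vip: irrelevant_threshold must be <= relevant_threshold")
  s <- as.numeric(scores)
  label <- ifelse(s > relevant_threshold, "relevant",
                  ifelse(s < irrelevant_threshold, "irrelevant",
                         "intermediate"))
  label <- factor(label, levels = c("relevant", "intermediate", "irrelevant"))
  list(label = label, counts = table(label))
}

#' @export
print.vip_scores <- function(x, ...) {
  cc <- attr(x, "component_counts")
  cat("vip_scores (", attr(x, "variant"), "): ", length(x),
      " variables, l = ", cc[["l"]], ", l_o = ", cc[["l_o"]], "\n", sep = "")
  cat("  range [", format(min(x), digits = 4), ", ",
      format(max(x), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Write VIP scores as a TSV table
#'
#' @param scores a `vip_scores` object.
#' @param path output file.
#' @param ... passed to [classify_by_vip()].
#' @return The written data frame, invisibly.
#' @export
write_vip_tsv <- function(scores, path, ...) {
  wl <- attr(scores, "wavelengths")
  if (is.null(wl)) wl <- seq_along(scores)
  df <- data.frame(wavelength = wl, score = as.numeric(scores),
                   variant = attr(scores, "variant"),
                   label = classify_by_vip(scores, ...)$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
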