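#' Run a scenario-by-method Monte Carlo benchmark
#'
#' For each scenario, datasets are regenerated `repetitions` times
#' (coefficients redrawn each repetition; the repetition seed is
#' `scenario seed + repetition index`) and every method is fitted on
#' the same data with the same cross-validation folds. The summary is
#' the mean over repetitions of the selected component count and the
#' RMSE, R2, RPD and SE statistics. Two metric flavours are recorded
#' per repetition: `"fit"` statistics from refitting on all samples at
#' the CV-selected component count (the flavour whose magnitudes match
#' the published benchmark and the summary default) and `"cv"`
#' statistics from the pooled out-of-fold predictions. A method that
#' fails on a scenario (e.g. too few samples for the requested
#' components) is reported as `NA` for that scenario.
#'
#' @param scenarios list of [simulation_config()] objects (a single
#'   config is accepted too).
#' @param methods character vector from
#'   `c("plsr", "vip", "mcuve", "mod-vip-mcuve")`.
#' @param repetitions Monte Carlo repetitions per scenario (>= 1).
#' @param cv_spec a [cv_spec()] shared by all methods.
#' @param mcuve_params an [mcuve_params()] for the MCUVE-based methods.
#' @param metric_flavor which flavour the summary reports: `"fit"`
#'   (default) or `"cv"`; both are kept in `raw`.
#' @return An object of class `scenario_study`: a data frame `summary`
#'   with columns n, m, IV, Method, nPLS, RMSE, R2, RPD, SE, plus a
#'   `raw` data frame of per-repetition values in both flavours
#'   (suffixes `_fit` and `_cv`).
#' @export
run_scenario_study <- function(scenarios, methods, repetitions,
                               cv_spec = wavesel::cv_spec(),
                               mcuve_params = wavesel::mcuve_params(),
                               metric_flavor = c("fit", "cv")) {
  metric_flavor <- match.arg(metric_flavor)
  if (inherits(scenarios, "simulation_config")) scenarios <- list(scenarios)
  methods <- as.character(methods)
  known <- c("plsr", "vip", "mcuve", "mod-vip-mcuve")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop("run_scenario_study: unknown method identifier(s): ",
         paste(bad, collapse = ", "))
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("run_scenario_study: repetitions must be >= 1")

  rows <- vector("list", length(scenarios) * length(methods) * repetitions)
  ri <- 0L
  for (sc in scenarios) {
    stopifnot(inherits(sc, "simulation_config"))
    for (rep in seq_len(repetitions)) {
      cfg <- sc
      cfg$seed <- sc$seed + rep
      ds <- generate_dataset(cfg)
      # cap the CV grid at what the scenario supports
      spec_r <- cv_spec
      spec_r$seed <- cv_spec$seed + rep
      mc_r <- mcuve_params
      mc_r$seed <- mcuve_params$seed + rep
      folds <- make_folds(cfg$n, spec_r)
      for (method in methods) {
        ri <- ri + 1L
        res <- tryCatch(
          suppressWarnings(
            run_comparator(ds, method, cv_spec = spec_r,
                           mcuve_params = mc_r, folds = folds)),
          error = function(e) NULL)
        grab <- function(res, slot, stat)
          if (is.null(res)) NA_real_ else res[[slot]][[stat]]
        rows[[ri]] <- data.frame(
          n = cfg$n, m = cfg$m, IV = cfg$iv_fraction,
          Method = method, repetition = rep,
          nPLS = if (is.null(res)) NA_integer_ else res$n_components,
          RMSE_fit = grab(res, "fit_metrics", "rmse"),
          R2_fit = grab(res, "fit_metrics", "r2"),
          RPD_fit = grab(res, "fit_metrics", "rpd"),
          SE_fit = grab(res, "fit_metrics", "se"),
          RMSE_cv = grab(res, "metrics", "rmse"),
          R2_cv = grab(res, "metrics", "r2"),
          RPD_cv = grab(res, "metrics", "rpd"),
          SE_cv = grab(res, "metrics", "se"))
      }
    }
  }
  raw <- do.call(rbind, rows)
  sfx <- paste0("_", metric_flavor)
  stat_cols <- c("nPLS", paste0(c("RMSE", "R2", "RPD", "SE"), sfx))
  summary <- stats::aggregate(
    raw[, stat_cols],
    by = raw[, c("n", "m", "IV", "Method")],
    FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  names(summary) <- sub(sfx, "", names(summary), fixed = TRUE)
  # preserve scenario-then-method presentation order
  key <- vapply(scenarios, function(s)
    paste(s$n, s$m, s$iv_fraction), character(1))
  summary <- summary[order(match(paste(summary$n, summary$m, summary$IV), key),
                           match(summary$Method, methods)), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, raw = raw,
                 methods = methods, repetitions = repetitions,
                 metric_flavor = metric_flavor),
            class = "scenario_study")
}

#' @export
print.scenario_study <- function(x, ...) {
  cat("scenario_study: ", x$repetitions, " repetitions, methods: ",
      paste(x$methods, collapse = ", "), "\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a scenario-study summary as TSV
#'
#' @param study a `scenario_study`.
#' @param path output file.
#' @return The summary data frame, invisibly.
#' @export
write_study_tsv <- function(study, path) {
  utils::write.table(study$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study$summary)
}

#' Scenario grid of the simulation benchmark
#'
#' The fifteen (n, m, IV) combinations of the published benchmark:
#' paired levels n in (40, 60, 150, 400, 600) with IV in
#' (0.10, 0.20, 0.40, 0.60, 0.80), crossed with m in (41, 101, 201).
#'
#' @param seed base seed given to every scenario.
#' @return A list of [simulation_config()] objects.
#' @export
benchmark_scenarios <- function(seed = 1L) {
  n_iv <- list(c(40, 0.10), c(60, 0.20), c(150, 0.40),
               c(400, 0.60), c(600, 0.80))
  out <- list()
  for (ni in n_iv)
    for (m in c(41L, 101L, 201L))
      out[[length(out) + 1L]] <-
        simulation_config(ni[1L], m, ni[2L], seed = seed)
  out
}
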