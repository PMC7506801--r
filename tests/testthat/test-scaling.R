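test_that("auto-scaling standardizes every column", {
  set.seed(50)
  ds <- spectra_dataset(matrix(rnorm(500, 3, 2), 50, 10), rnorm(50))
  sc <- auto_scale(ds)
  expect_lt(max(abs(colMeans(sc$data$X))), 1e-12)
  expect_equal(apply(sc$data$X, 2, sd), rep(1, 10), tolerance = 1e-12)
  # idempotence on already-standardized input
  sc2 <- auto_scale(sc$data)
  expect_equal(sc2$data$X, sc$data$X, tolerance = 1e-12)
  # zero-variance columns are named in the error
  bad <- spectra_dataset(cbind(rnorm(10), 1), rnorm(10))
  expect_error(auto_scale(bad), "zero-variance column\\(s\\): 2")
})

test_that("diagonal scaling multiplies columns and validates factors", {
  X <- matrix(1:6, 2, 3)
  ds <- spectra_dataset(X, c(1, 2), wavelengths = c(100, 200, 300))
  out <- apply_scaling(ds, scaling_matrix(c(2, 0, 1)))
  expect_equal(out$X[, 1], 2 * X[, 1])
  expect_true(all(out$X[, 2] == 0))
  expect_equal(out$X[, 3], X[, 3])
  expect_identical(out$wavelengths, c(100, 200, 300))
  # identity leaves data untouched
  expect_equal(apply_scaling(ds, rep(1, 3))$X, ds$X)
  expect_error(scaling_matrix(c(1, -0.1, 2)), "factors must be")
  expect_error(apply_scaling(ds, c(1, 2)), "factors for")
  # factors from a VIP vector match the elementwise product oracle
  v <- c(0.5, 1.5, 2.5)
  expect_equal(apply_scaling(ds, scaling_matrix(v))$X,
               ds$X * rep(v, each = 2))
})

test_that("uniform scaling leaves PLS predictions unchanged, non-uniform not", {
  ds <- toy_dataset(20, 5, seed = 51, noise = 0.5)
  base <- predict(fit_plsr(ds, 3), ds)
  uni <- apply_scaling(ds, rep(2.7, 5))
  expect_equal(predict(fit_plsr(uni, 3), uni), base, tolerance = 1e-8)
  nonuni <- apply_scaling(ds, c(5, 1, 1, 1, 1))
  pred_nonuni <- predict(fit_plsr(nonuni, 3), nonuni)
  expect_gt(max(abs(pred_nonuni - base)), 1e-6)
})

test_that("a zero factor removes all influence of that variable", {
  ds <- toy_dataset(20, 5, seed = 52)
  zeroed <- apply_scaling(ds, c(1, 1, 0, 1, 1))
  fit <- fit_plsr(zeroed, 3)
  # the zeroed column gets an exactly zero coefficient, so perturbing it
  # in new data leaves predictions bit-identical
  expect_identical(fit$regression_vector[[3]], 0)
  perturbed <- zeroed$X
  perturbed[, 3] <- perturbed[, 3] + 1e6
  expect_identical(predict(fit, perturbed), predict(fit, zeroed$X))
})

test_that("pipeline is deterministic under fixed seeds", {
  ds <- generate_dataset(simulation_config(40, 21, 0.2, seed = 60))
  args <- list(ds, mcuve_params = mcuve_params(n_resamples = 30, seed = 4),
               cv_spec = cv_spec(n_folds = 5, seed = 4))
  a <- do.call(mod_vip_mcuve, args)
  b <- do.call(mod_vip_mcuve, args)
  expect_identical(a$selection_report, b$selection_report)
  expect_identical(a$final_model$regression_vector,
                   b$final_model$regression_vector)
  expect_identical(a$cutoff_value, b$cutoff_value)
})

test_that("identical predictor copies receive identical scaling factors", {
  set.seed(61)
  x <- rnorm(30)
  y <- 2 * x + rnorm(30, 0, 0.1)
  ds <- spectra_dataset(cbind(x, x, x), y)
  pr <- suppressWarnings(
    mod_vip_mcuve(ds, opls_spec = list(n_predictive = 1, n_orthogonal = 0),
                  mcuve_params = mcuve_params(n_resamples = 30,
                                              n_components = 1, seed = 2),
                  cv_spec = cv_spec(n_folds = 5, max_components = 1,
                                    seed = 2)))
  f <- pr$selection_report$final_factor
  expect_equal(f[2], f[1], tolerance = 1e-6)
  expect_equal(f[3], f[1], tolerance = 1e-6)
  # uniform factors: predictions match a plain 1-component PLSR
  plain <- predict(fit_plsr(ds, 1), ds)
  piped <- predict(pr$final_model, pr$step3_scaled)
  expect_equal(piped, plain, tolerance = 1e-6)
})

test_that("step3_from switches between cumulative and raw rescaling", {
  ds <- generate_dataset(simulation_config(30, 15, 0.2, seed = 62))
  mp <- mcuve_params(n_resamples = 30, n_components = 3, seed = 5)
  cs <- cv_spec(n_folds = 5, seed = 5)
  cum <- mod_vip_mcuve(ds, mcuve_params = mp, cv_spec = cs)
  raw <- mod_vip_mcuve(ds, mcuve_params = mp, cv_spec = cs,
                       step3_from = "raw")
  lam2 <- abs(cum$step2_result$reliability)
  expect_equal(cum$step3_scaled$X,
               sweep(cum$step1_scaled$X, 2, lam2, "*"), tolerance = 1e-12)
  expect_equal(raw$step3_scaled$X,
               sweep(ds$X, 2, abs(raw$step2_result$reliability), "*"),
               tolerance = 1e-12)
})

test_that("comparator methods share one fold assignment and yield metrics", {
  ds <- generate_dataset(simulation_config(40, 21, 0.2, seed = 63))
  cs <- cv_spec(n_folds = 5, seed = 9)
  folds <- wavesel:::make_folds(40, cs)
  mp <- mcuve_params(n_resamples = 30, n_components = 3, seed = 9)
  out <- lapply(c("plsr", "vip", "mcuve", "mod-vip-mcuve"), function(m)
    run_comparator(ds, m, cv_spec = cs, mcuve_params = mp, folds = folds))
  for (res in out) {
    expect_s3_class(res$metrics, "evaluation_metrics")
    expect_s3_class(res$fit_metrics, "evaluation_metrics")
    expect_true(res$n_components >= 1)
    # stored metrics match a recomputation from the stored predictions
    k <- res$n_components
    expect_equal(res$metrics$rmse,
                 sqrt(mean((ds$y - res$cv$predictions[, k])^2)),
                 tolerance = 1e-12)
  }
  expect_error(run_comparator(ds, "boosting"), "arg")
})
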