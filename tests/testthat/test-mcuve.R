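test_that("noise augmentation books dimensions and is seed-stable", {
  ds <- toy_dataset(12, 5, seed = 40)
  p <- mcuve_params(n_resamples = 10, seed = 5)
  aug <- augment_noise(ds, p)
  expect_identical(ncol(aug$data$X), 10L)       # default count = m
  expect_identical(aug$real_index, 1:5)
  expect_identical(aug$noise_index, 6:10)
  aug2 <- augment_noise(ds, p)
  expect_identical(aug$data$X, aug2$data$X)
  # amplitude bounds the artificial sum of squares
  p_small <- mcuve_params(n_resamples = 10, noise_amplitude = 1e-10, seed = 5)
  aug3 <- augment_noise(ds, p_small)
  expect_lte(max(colSums(aug3$data$X[, 6:10]^2)), 1e-20 * nrow(ds$X))
})

test_that("reliability is the mean/sd ratio with r-1 denominator", {
  B <- cbind(c(1, 3), c(2, 2), c(0, 0))
  rel <- wavesel:::compute_reliability(B)
  expect_equal(rel$reliability[1], 2 / sqrt(2))     # sd({1,3}) = sqrt(2)
  expect_identical(rel$reliability[2], Inf)         # zero spread, mean > 0
  expect_true(is.nan(rel$reliability[3]))           # all-zero column
})

test_that("sub-model reliabilities separate informative from noise columns", {
  wins <- 0L
  for (s in 1:9) {
    ds <- generate_dataset(simulation_config(60, 101, 0.2, seed = 200 + s))
    p <- mcuve_params(n_resamples = 50, n_components = 5, seed = s)
    res <- mc_reliability(augment_noise(ds, p), p)
    med_imp <- median(abs(res$reliability[ds$important_index_set]))
    med_art <- median(abs(res$reliability_artificial))
    wins <- wins + (med_imp > med_art)
  }
  expect_gte(wins, 5L)   # majority of seeds
})

test_that("reliability is invariant to permuting the resample records", {
  ds <- toy_dataset(20, 5, seed = 41)
  p <- mcuve_params(n_resamples = 30, n_components = 2, seed = 7)
  res <- mc_reliability(augment_noise(ds, p), p)
  set.seed(1)
  B_perm <- res$coefficient_matrix[sample(30), ]
  rel <- wavesel:::compute_reliability(B_perm)
  expect_equal(rel$reliability[res$real_index], unname(res$reliability),
               tolerance = 1e-12)
})

test_that("classical cutoff is the maximum absolute noise reliability", {
  res <- fake_mcuve_result(real = c(5, 0.5, -4), artificial = c(-3, 2))
  res <- classical_cutoff(res)
  expect_identical(res$cutoff_value, 3)
  expect_identical(res$selected_mask, c(TRUE, FALSE, TRUE))
  # brute-force oracle on random vectors
  set.seed(2)
  ca <- rnorm(50)
  res2 <- classical_cutoff(fake_mcuve_result(rnorm(5), ca))
  expect_identical(res2$cutoff_value, max(abs(ca)))
  # all real reliabilities above the cutoff: nothing removed
  res3 <- classical_cutoff(fake_mcuve_result(c(10, -12), c(0.1, -0.2)))
  expect_true(all(res3$selected_mask))
  expect_error(classical_cutoff(fake_mcuve_result(1, numeric(0))),
               "no artificial")
})

test_that("tolerance k factor approaches z_gamma and matches noncentral t", {
  k_inf <- tolerance_k(0.95, 0.05, 1e6)
  expect_equal(k_inf$k_factor, qnorm(0.95), tolerance = 0.01)
  # exact one-sided normal tolerance factor via the noncentral-t construction
  k500 <- tolerance_k(0.95, 0.05, 500)
  k_exact <- suppressWarnings(
    qt(0.95, df = 499, ncp = qnorm(0.95) * sqrt(500)) / sqrt(500))
  expect_lt(abs(k500$k_factor - k_exact) / k_exact, 0.02)
  # monotone in the covered proportion
  expect_gt(tolerance_k(0.99, 0.05, 500)$k_factor, k500$k_factor)
  expect_error(tolerance_k(0.95, 0.05, 2), "r must be")
  # extreme confidence at tiny r drives the constant a below zero
  expect_error(tolerance_k(0.95, 1e-5, 3), "a =")
})

test_that("robust cutoff follows median + k * MAD", {
  tol1 <- tolerance_k(0.95, 0.05, 100)
  # degenerate spread: cutoff equals the constant
  resk <- robust_cutoff(fake_mcuve_result(c(1, 2), rep(4.2, 5)), tol1)
  expect_equal(resk$cutoff_value, 4.2)
  # hand computation with the consistency factor disabled and k = 1
  tol_k1 <- tol1; tol_k1$k_factor <- 1
  res3 <- robust_cutoff(fake_mcuve_result(c(1, 4), c(1, 2, 3)), tol_k1,
                        mad_constant = 1)
  expect_equal(res3$cutoff_value, 3)          # 2 + 1 * 1
  expect_identical(res3$selected_mask, c(FALSE, TRUE))   # signed rule, > 3
})

test_that("robust cutoff excludes roughly the target noise proportion", {
  set.seed(3)
  ca <- rnorm(1e4)
  tol <- tolerance_k(0.95, 0.05, 1e4)
  res <- robust_cutoff(fake_mcuve_result(rnorm(3), ca), tol)
  frac_above <- mean(ca > res$cutoff_value)
  expect_lte(frac_above, 1 - 0.95 + 0.02)
})

test_that("robust cutoff resists gross tail outliers, classical does not", {
  set.seed(4)
  ca <- rnorm(200)
  base <- fake_mcuve_result(rnorm(5), ca)
  tol <- tolerance_k(0.95, 0.05, 200)
  clean_robust <- robust_cutoff(base, tol)$cutoff_value
  clean_classical <- classical_cutoff(base)$cutoff_value
  # corrupt the largest quartile so the clean median/MAD dominate
  for (frac in c(0.10, 0.25)) {
    k_out <- round(frac * 200)
    top <- order(ca, decreasing = TRUE)[seq_len(k_out)]
    ca_bad <- ca
    ca_bad[top] <- ca[top] * 1e6
    bad <- fake_mcuve_result(rnorm(5), ca_bad)
    moved <- abs(robust_cutoff(bad, tol)$cutoff_value - clean_robust) /
      abs(clean_robust)
    expect_lt(moved, 0.10)
    expect_gt(classical_cutoff(bad)$cutoff_value, 1e5)
  }
  expect_lt(clean_classical, 10)
})

test_that("zero-spread columns are reported as maximally reliable", {
  ds <- toy_dataset(20, 4, seed = 42)
  X <- ds$X
  X <- cbind(X, constant = 5)   # constant column: coefficient always 0
  ds2 <- spectra_dataset(X, ds$y)
  p <- mcuve_params(n_resamples = 10, n_components = 2, seed = 3)
  expect_warning(res <- mc_reliability(augment_noise(ds2, p), p),
                 "zero coefficient spread")
  expect_true(is.nan(res$reliability[5]))
})

test_that("reliability tables export as TSV", {
  res <- classical_cutoff(fake_mcuve_result(c(2, -1), c(0.3, -0.4)))
  path <- tempfile(fileext = ".tsv")
  df <- write_mcuve_tsv(res, path)
  back <- read.delim(path)
  expect_identical(nrow(back), 4L)
  expect_identical(back$artificial, c(FALSE, FALSE, TRUE, TRUE))
})
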