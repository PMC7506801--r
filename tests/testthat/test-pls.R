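test_that("noise-free rank-1 response is fit exactly by one component", {
  ds <- rank1_dataset()
  fit <- fit_plsr(ds, 1)
  mets <- evaluate(ds$y, predict(fit, ds))
  expect_equal(mets$r2, 1, tolerance = 1e-10)
  expect_lt(mets$rmse, 1e-8 * sd(ds$y))
})

test_that("full-component PLSR equals the least-squares solution", {
  set.seed(10)
  X <- matrix(rnorm(40), 10, 4)
  y <- drop(X %*% c(1, -2, 0.5, 3)) + rnorm(10)
  ds <- spectra_dataset(X, y)
  fit <- fit_plsr(ds, 4)
  b_ls <- unname(coef(lm(y ~ X))[-1])          # normal-equations oracle
  expect_equal(unname(fit$regression_vector), b_ls, tolerance = 1e-8)
  expect_equal(predict(fit, ds), unname(fitted(lm(y ~ X))), tolerance = 1e-8)
})

test_that("NIPALS scores are mutually orthogonal and weights unit-norm", {
  ds <- toy_dataset(25, 8, seed = 6)
  fit <- fit_plsr(ds, 5)
  G <- crossprod(fit$x_scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  expect_equal(colSums(fit$weights^2), rep(1, 5), tolerance = 1e-10)
})

test_that("direct and standard regression-vector expressions agree", {
  # the closed-form b = X'U (V'X X'U)^-1 V'y against W (P'W)^-1 q
  for (seed in 1:3) {
    ds <- toy_dataset(18, 5, seed = seed)
    fit <- fit_plsr(ds, 3)
    b_direct <- wavesel:::regression_vector_direct(fit, ds)
    expect_equal(b_direct, unname(fit$regression_vector), tolerance = 1e-8)
  }
})

test_that("prediction reproduces training fits and handles centering", {
  ds <- toy_dataset(20, 6, seed = 7)
  fit <- fit_plsr(ds, 3)
  expect_equal(predict(fit, ds$X), predict(fit, ds))
  expect_equal(predict(fit, ds$X[4, , drop = FALSE]),
               predict(fit, ds)[4])
  # a row at the training column means predicts the training mean of y
  expect_equal(predict(fit, matrix(colMeans(ds$X), 1)), mean(ds$y),
               tolerance = 1e-10)
  expect_error(predict(fit, ds$X[, 1:3]), "columns")
})

test_that("degenerate deflation is reported with the component index", {
  ds <- rank1_dataset(n = 15, m = 4)   # X residual orthogonal to y after 1
  expect_error(fit_plsr(ds, 3, on_deficient = "error"),
               "degenerate component 2")
  expect_warning(fit2 <- fit_plsr(ds, 3), "degenerate component 2")
  expect_identical(fit2$n_components, 1L)
})

test_that("training error is monotone and explained SSY non-decreasing", {
  ds <- toy_dataset(30, 10, seed = 8, noise = 0.5)
  fit <- fit_plsr(ds, 8)
  rmse_k <- vapply(1:8, function(k)
    sqrt(mean((ds$y - predict(fit, ds, n_components = k))^2)), numeric(1))
  expect_true(all(diff(rmse_k) <= 1e-10))
  expect_true(all(fit$ssy_per_component >= -1e-12))
  expect_true(all(cumsum(fit$ssy_per_component) >= 0))
})

test_that("deflation conserves the total sum of squares of X", {
  ds <- toy_dataset(25, 7, seed = 9)
  fit <- fit_plsr(ds, 5)
  Xc <- sweep(ds$X, 2, colMeans(ds$X))
  lhs <- sum(fit$x_residual^2) + sum(fit$ssx_per_component)
  expect_equal(lhs, sum(Xc^2), tolerance = 1e-6)
})

test_that("OPLS with no orthogonal components reduces to PLSR", {
  ds <- toy_dataset(20, 6, seed = 11)
  opls <- fit_opls(ds, 3, 0)
  pls <- fit_plsr(ds, 3)
  expect_equal(opls$predictive$regression_vector, pls$regression_vector)
  expect_equal(opls$ssy_per_component, pls$ssy_per_component)
  expect_identical(opls$n_orthogonal, 0L)
})

test_that("orthogonal scores are uncorrelated with the response", {
  ds <- toy_dataset(30, 8, seed = 12, noise = 1)
  opls <- fit_opls(ds, 2, 3)
  for (j in 1:3)
    expect_lt(abs(cor(opls$orthogonal$scores[, j], ds$y)), 1e-6)
})

test_that("a planted y-orthogonal structure lands in the orthogonal block", {
  toy <- orthogonal_structure_dataset()
  opls <- fit_opls(toy$data, 2, 1)
  # the injected direction dominates X: the orthogonal component captures
  # more SSX than any predictive component
  expect_gt(opls$ssx_per_orthogonal[1], max(opls$ssx_per_component))
  # and aligns with the planted score direction (projection oracle)
  alignment <- abs(cor(opls$orthogonal$scores[, 1], toy$t_o))
  expect_gt(alignment, 0.95)
})

test_that("model JSON serialization round-trips the regression vector", {
  ds <- toy_dataset(15, 5, seed = 13)
  fit <- fit_plsr(ds, 2)
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$regression_vector, unname(fit$regression_vector),
               tolerance = 1e-12)
  expect_identical(obj$n_components, 2L)
})
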