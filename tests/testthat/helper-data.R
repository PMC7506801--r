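# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# random dense dataset with a planted linear signal
toy_dataset <- function(n = 20, m = 6, seed = 1, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  b <- seq_len(m) / m
  y <- drop(X %*% b) + rnorm(n, 0, noise)
  spectra_dataset(X, y)
}

# noise-free rank-1 design: every column is a multiple of one latent
# direction and y is proportional to it, so a single component fits
# exactly (on any subsample) and deflation then degenerates
rank1_dataset <- function(n = 15, m = 4, seed = 2) {
  set.seed(seed)
  x <- rnorm(n)
  load <- c(1, runif(m - 1, 0.5, 2))
  spectra_dataset(outer(x, load), 3 * x)
}

# two columns engineered so the single NIPALS weight vector is exactly
# (1, 0): column 1 equals y, column 2 is orthogonal to y
vip_weight_dataset <- function(n = 12, seed = 3) {
  set.seed(seed)
  y <- rnorm(n)
  yc <- y - mean(y)
  z <- rnorm(n)
  z <- z - mean(z)
  z <- z - sum(z * yc) / sum(yc^2) * yc   # exactly y-orthogonal, centered
  spectra_dataset(cbind(y, z), y)
}

# dataset with a planted y-orthogonal rank-1 structure dominating X
orthogonal_structure_dataset <- function(n = 20, m = 6, seed = 4) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  y <- X[, 1] + 0.1 * rnorm(n)
  yc <- y - mean(y)
  t_o <- rnorm(n)
  t_o <- t_o - mean(t_o)
  t_o <- t_o - sum(t_o * yc) / sum(yc^2) * yc   # y-orthogonal direction
  p_o <- rnorm(m)
  X <- X + 5 * tcrossprod(t_o, p_o)             # large orthogonal variation
  list(data = spectra_dataset(X, y), t_o = t_o)
}

# minimal mcuve_result carrying prescribed reliabilities
fake_mcuve_result <- function(real, artificial) {
  structure(list(reliability = real, reliability_artificial = artificial,
                 real_index = seq_along(real),
                 noise_index = length(real) + seq_along(artificial),
                 cutoff_value = NA_real_, cutoff_kind = NA_character_,
                 selected_mask = NULL),
            class = "mcuve_result")
}
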