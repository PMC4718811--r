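# Shared fixture builders. Cohorts are generated in code at test time; the
# "small grid" halves the stereotaxic frame (VOI table at scale 5) so spheres
# fit a 20 x 24 x 6 grid at the standard x10 spacing.

small_grid_config <- function(group_sizes, seed = 1L, voi_covariance = NULL,
                              regional_means = NULL, noise_sd = 0.02,
                              smoothing_fwhm_mm = 4) {
  synthetic_config(grid_shape = c(20L, 24L, 6L),
                   origin_mm = c(-38.75, -46.5, 0),
                   voi_table = default_voi_table(scale = 5),
                   group_sizes = group_sizes,
                   voi_covariance = voi_covariance,
                   regional_means = regional_means,
                   noise_sd = noise_sd,
                   smoothing_fwhm_mm = smoothing_fwhm_mm,
                   seed = seed)
}

# Two-group config with identical planted distributions (a true null).
null_two_group_config <- function(n_per_group = 15, seed = 1L) {
  R <- 0.08^2 * voi_correlation_model(0.3)
  mu <- matrix(1, 8, 2, dimnames = list(default_voi_table()$abbreviation,
                                        c("a", "b")))
  small_grid_config(group_sizes = c(a = n_per_group, b = n_per_group),
                    seed = seed,
                    voi_covariance = list(a = R, b = R),
                    regional_means = mu)
}

# Covariance with a single planted off-diagonal correlation between two VOIs.
single_edge_covariance <- function(r, voi_i = "MedF", voi_j = "Rsp",
                                   sd = 0.08) {
  abbr <- default_voi_table()$abbreviation
  R <- diag(8)
  dimnames(R) <- list(abbr, abbr)
  R[voi_i, voi_j] <- R[voi_j, voi_i] <- r
  sd^2 * R
}

# Plain VOI matrix drawn straight from a multivariate normal (no imaging),
# for unit tests of the statistics that do not need volumes.
draw_voi_matrix <- function(n, Sigma = diag(8), mu = rep(1, 8), group = "g",
                            seed = 1L) {
  abbr <- default_voi_table()$abbreviation
  set.seed(seed)
  ev <- eigen(Sigma, symmetric = TRUE)
  root <- ev$vectors %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0)))
  m <- sweep(matrix(rnorm(n * 8), n) %*% root, 2, mu, "+")
  dimnames(m) <- list(sprintf("r%02d", seq_len(n)), abbr)
  structure(m, group = group, class = c("voi_matrix", "matrix"))
}

# Tiny geometric volume for smoothing / masking unit tests.
toy_volume <- function(values = NULL, dims = c(9L, 9L, 7L),
                       spacing = c(1, 1, 2), origin = c(0, 0, 0)) {
  if (is.null(values)) values <- array(0, dim = dims)
  brain_volume(values, spacing, origin)
}
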