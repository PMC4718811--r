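#' Default planted interregional correlation structure
#'
#' Across-subject correlation of VOI loadings for one age group: homologous
#' left-right pairs correlate at `r_homologous`, hippocampal (limbic) edges
#' stay at `r_limbic` across ages, and all edges among the cortical
#' anterior-posterior system (MedF, Rsp, motor, somatosensory) share `r_ap`,
#' which is the maturation dial — it strengthens with age in the default
#' cohort.
#'
#' @param r_ap anterior-posterior coupling in [0, 1).
#' @param r_homologous left-right homologous coupling.
#' @param r_limbic hippocampal edge coupling.
#' @return 8x8 correlation matrix in default VOI order.
#' @export
voi_correlation_model <- function(r_ap, r_homologous = 0.5, r_limbic = 0.2) {
  abbr <- default_voi_table()$abbreviation
  R <- diag(8)
  dimnames(R) <- list(abbr, abbr)
  cortical <- c("MedF", "Rsp", "Mot_L", "Mot_R", "SS_L", "SS_R")
  R[cortical, cortical] <- r_ap
  for (p in list(c("Hp_L", "Hp_R"), c("Mot_L", "Mot_R"), c("SS_L", "SS_R")))
    R[p[1], p[2]] <- R[p[2], p[1]] <- r_homologous
  hp <- c("Hp_L", "Hp_R")
  R[hp, setdiff(abbr, hp)] <- r_limbic
  R[setdiff(abbr, hp), hp] <- r_limbic
  R[hp, hp] <- r_homologous
  diag(R) <- 1
  R
}

.default_regional_means <- function() {
  abbr <- default_voi_table()$abbreviation
  m <- cbind(`5wk`  = c(1.00, 1.00, 0.95, 1.05, 0.95, 0.95, 1.00, 1.00),
             `10wk` = c(0.98, 0.98, 1.02, 1.00, 1.00, 1.00, 1.02, 1.02),
             `15wk` = c(0.96, 0.96, 1.08, 0.96, 1.04, 1.04, 1.04, 1.04))
  rownames(m) <- abbr
  m
}

.check_psd <- function(S, label) {
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop(sprintf("voi_covariance[%s] is not symmetric", label))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop(sprintf("voi_covariance[%s] is not positive semi-definite (min eigenvalue %.3g)",
                 label, min(ev)))
  invisible(TRUE)
}

.safe_cov2cor <- function(S) {
  d <- sqrt(diag(S))
  R <- diag(nrow(S))
  dimnames(R) <- dimnames(S)
  pos <- d > 0
  if (any(pos))
    R[pos, pos] <- S[pos, pos] / (d[pos] %o% d[pos])
  diag(R) <- 1
  R
}

# Deterministic PSD square root for multivariate normal draws.
.mvn_draw <- function(n, mu, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  root <- ev$vectors %*% (t(ev$vectors) * sqrt(lam))
  z <- matrix(stats::rnorm(n * length(mu)), n)
  sweep(z %*% root, 2, mu, "+")
}

#' Configuration of a synthetic multi-subject PET cohort
#'
#' Describes a longitudinal study design of pre-aligned 3D volumes: three age
#' groups (default 30/30/28 subjects at 5, 10 and 15 weeks), a fixed smooth
#' ellipsoidal "brain" background, subject-specific scalar loadings on eight
#' spherical VOI supports at the default stereotaxic centres (drawn from a
#' multivariate normal with group-specific means and covariance), additive
#' i.i.d. Gaussian voxel noise, and Gaussian intrinsic smoothness. Everything
#' downstream — voxelwise contrasts, ICA, connectivity, efficiency — can be
#' validated against the planted ground truth.
#'
#' Defaults put the study's maturation signature into the cohort: anterior
#' regional uptake rises and posterior/limbic uptake falls with age, while
#' anterior-posterior across-subject coupling strengthens (r_ap 0.15, 0.45,
#' 0.65 at 5, 10, 15 weeks).
#'
#' @param grid_shape integer(3) voxel grid (default 40 x 48 x 12).
#' @param voxel_spacing_mm numeric(3), mm in the x10-scaled frame
#'   (default 3.875, 3.875, 7.75).
#' @param origin_mm mm coordinate of voxel `[1,1,1]` centre relative to bregma.
#' @param group_sizes named integer vector, subjects per age group, each >= 2.
#' @param regional_means VOIs x groups matrix of planted mean regional signal
#'   (arbitrary uptake units, added on the background inside each sphere).
#' @param voi_covariance named list (one per group) of 8x8 symmetric PSD
#'   covariance matrices of the across-subject VOI loadings.
#' @param noise_sd SD of i.i.d. voxel noise (uptake units).
#' @param smoothing_fwhm_mm intrinsic smoothness applied after signal
#'   injection (mm, x10 frame).
#' @param background_amplitude peak intensity of the smooth background dome.
#' @param voi_radius_mm radius of the planted spherical supports (mm).
#' @param voi_table VOI centre table (default [default_voi_table()]).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config including this seed.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(40L, 48L, 12L),
                             voxel_spacing_mm = c(3.875, 3.875, 7.75),
                             origin_mm = c(-77.5, -90, 0),
                             group_sizes = c(`5wk` = 30L, `10wk` = 30L,
                                             `15wk` = 28L),
                             regional_means = NULL,
                             voi_covariance = NULL,
                             noise_sd = 0.02,
                             smoothing_fwhm_mm = 4,
                             background_amplitude = 1,
                             voi_radius_mm = 8,
                             voi_table = default_voi_table(),
                             seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("`grid_shape` must be 3 positive integers")
  if (any(voxel_spacing_mm <= 0)) stop("voxel spacings must be > 0")
  if (is.null(names(group_sizes)))
    stop("`group_sizes` must be a named vector (age-group labels)")
  if (any(group_sizes < 2))
    stop("each group needs at least 2 subjects")
  n_voi <- nrow(voi_table)
  groups <- names(group_sizes)
  if (is.null(regional_means)) {
    regional_means <- .default_regional_means()
    if (!all(groups %in% colnames(regional_means)))
      regional_means <- matrix(1, n_voi, length(groups),
                               dimnames = list(voi_table$abbreviation, groups))
  }
  regional_means <- regional_means[, groups, drop = FALSE]
  if (nrow(regional_means) != n_voi)
    stop("`regional_means` must have one row per VOI")
  if (is.null(voi_covariance)) {
    r_ap <- c(0.15, 0.45, 0.65)[seq_along(groups)]
    r_ap[is.na(r_ap)] <- 0.65
    loading_sd <- 0.08
    voi_covariance <- lapply(r_ap, function(r)
      loading_sd^2 * voi_correlation_model(r))
    names(voi_covariance) <- groups
  }
  if (!all(groups %in% names(voi_covariance)))
    stop("`voi_covariance` must be a named list covering every group")
  for (g in groups) {
    S <- voi_covariance[[g]]
    if (!is.matrix(S) || any(dim(S) != n_voi))
      stop(sprintf("voi_covariance[%s] must be %d x %d", g, n_voi, n_voi))
    .check_psd(S, g)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (smoothing_fwhm_mm < 0) stop("`smoothing_fwhm_mm` must be >= 0")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 group_sizes = group_sizes,
                 regional_means = regional_means,
                 voi_covariance = voi_covariance[groups],
                 noise_sd = noise_sd,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 background_amplitude = background_amplitude,
                 voi_radius_mm = voi_radius_mm,
                 voi_table = voi_table,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Template volume (all zero) carrying the configured grid geometry.
.template_volume <- function(config) {
  brain_volume(array(0, dim = config$grid_shape),
               config$voxel_spacing_mm, config$origin_mm)
}

# Ellipsoidal brain mask and smooth background dome shared by all subjects.
.cohort_geometry <- function(config) {
  tmpl <- .template_volume(config)
  cc <- voxel_coordinates(tmpl)
  ctr <- vapply(cc, function(x) mean(range(x)), numeric(1))
  half <- vapply(cc, function(x) diff(range(x)) / 2, numeric(1))
  u2 <- lapply(1:3, function(a) ((cc[[a]] - ctr[a]) / (0.85 * half[a]))^2)
  q <- outer(outer(u2[[1]], u2[[2]], "+"), u2[[3]], "+")
  mask <- brain_mask(q <= 1, config$voxel_spacing_mm, config$origin_mm)
  bg <- config$background_amplitude * exp(-q / 0.72)
  list(template = tmpl, mask = mask,
       background = array(bg, dim = config$grid_shape))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws, for each age group, subject loadings from the configured
#' multivariate normal and builds each subject's volume as
#' background + sum_j loading_j * sphere_j + noise, followed by Gaussian
#' smoothing at the configured intrinsic FWHM. A single seeded random stream
#' drives the whole cohort, so identical configs give bit-identical volumes.
#'
#' @param config a `synthetic_config`.
#' @return list with `scans` (named list of `scan_set`, one per group),
#'   `mask` (the `brain_mask`), and `ground_truth` (planted per-group VOI
#'   correlation matrices with unit diagonal, planted regional means, the
#'   per-component planted spatial maps, and the background mean within each
#'   VOI sphere).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  geom <- .cohort_geometry(config)
  masks <- voi_masks(config$voi_table, geom$template, config$voi_radius_mm)
  idx <- lapply(masks, function(m) which(m$values != 0))
  set.seed(config$seed)
  groups <- names(config$group_sizes)
  scans <- vector("list", length(groups))
  names(scans) <- groups
  n_vox <- prod(config$grid_shape)
  for (g in groups) {
    n <- config$group_sizes[[g]]
    L <- .mvn_draw(n, config$regional_means[, g], config$voi_covariance[[g]])
    vols <- vector("list", n)
    for (i in seq_len(n)) {
      vals <- geom$background
      for (j in seq_along(idx)) vals[idx[[j]]] <- vals[idx[[j]]] + L[i, j]
      if (config$noise_sd > 0)
        vals <- vals + array(stats::rnorm(n_vox, sd = config$noise_sd),
                             dim = config$grid_shape)
      v <- brain_volume(vals, config$voxel_spacing_mm, config$origin_mm)
      if (config$smoothing_fwhm_mm > 0)
        v <- gaussian_smooth(v, config$smoothing_fwhm_mm)
      vols[[i]] <- v
    }
    scans[[g]] <- scan_set(vols, sprintf("r%02d", seq_len(n)), g)
  }
  comp <- split(seq_len(nrow(config$voi_table)), config$voi_table$ic)
  comp_maps <- lapply(comp, function(j) {
    m <- array(0, dim = config$grid_shape)
    for (jj in j) m[idx[[jj]]] <- 1
    m
  })
  bg_sm <- if (config$smoothing_fwhm_mm > 0) {
    gaussian_smooth(brain_volume(geom$background, config$voxel_spacing_mm,
                                 config$origin_mm),
                    config$smoothing_fwhm_mm)$values
  } else geom$background
  bgv <- vapply(idx, function(i) mean(bg_sm[i]), numeric(1))
  # Intrinsic smoothing attenuates each planted loading within its own
  # sphere and bleeds a little into close neighbours; the deterministic gain
  # matrix (entry [j, k]: mean over sphere j of the smoothed support k) lets
  # extracted means be compared with planted ones exactly.
  gain <- vapply(seq_along(idx), function(k) {
    if (config$smoothing_fwhm_mm == 0)
      return(as.numeric(seq_along(idx) == k))
    s <- array(0, dim = config$grid_shape)
    s[idx[[k]]] <- 1
    sm <- gaussian_smooth(brain_volume(s, config$voxel_spacing_mm,
                                       config$origin_mm),
                          config$smoothing_fwhm_mm)
    vapply(idx, function(i) mean(sm$values[i]), numeric(1))
  }, numeric(length(idx)))
  dimnames(gain) <- list(names(idx), names(idx))
  truth <- list(
    correlations = lapply(config$voi_covariance, .safe_cov2cor),
    means = config$regional_means,
    component_maps = comp_maps,
    voi_background_means = bgv,
    voi_signal_gain = gain
  )
  list(scans = scans, mask = geom$mask, ground_truth = truth,
       config = config)
}

#' Write a generated cohort to disk
#'
#' One NIfTI-1 volume per subject (filename `<group>_<subject>.nii.gz`), the
#' binary brain mask, a TSV manifest (subject_id, group, path) and a JSON
#' ground-truth file.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest as a data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (g in names(cohort$scans)) {
    ss <- cohort$scans[[g]]
    for (i in seq_along(ss$volumes)) {
      fn <- file.path(dir, sprintf("%s_%s.nii.gz", g, ss$subject_ids[i]))
      write_volume(ss$volumes[[i]], fn)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = ss$subject_ids[i], group = g, path = fn,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_mask(cohort$mask, file.path(dir, "mask.nii.gz"))
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(correlations = gt$correlations, means = gt$means,
         voi_background_means = gt$voi_background_means),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Plant spatially compact, low-overlap component maps
#'
#' Places `k` Gaussian blobs at distinct lattice positions spaced at least
#' six sigma apart, so pairwise spatial correlation is near zero. Used as
#' ground-truth sources for testing spatial ICA.
#'
#' @param k number of components (>= 1).
#' @param grid_shape integer(3) voxel grid.
#' @param sigma_vox blob SD in voxels (default 2).
#' @return list of `k` 3D arrays (peak value 1), with blob centres attached
#'   as attribute `centers`.
#' @export
plant_component_maps <- function(k, grid_shape, sigma_vox = 2) {
  if (!is.numeric(k) || k < 1) stop("`k` must be a positive integer")
  k <- as.integer(k)
  grid_shape <- as.integer(grid_shape)
  step <- ceiling(6 * sigma_vox)
  m <- pmax(1L, grid_shape %/% step)
  capacity <- prod(m)
  if (k > capacity)
    stop(sprintf("cannot place %d non-overlapping blobs on a %s grid (capacity %d)",
                 k, paste(grid_shape, collapse = "x"), capacity))
  centers <- as.matrix(expand.grid(lapply(1:3, function(a)
    grid_shape[a] * (2 * seq_len(m[a]) - 1) / (2 * m[a]))))[seq_len(k), ,
                                                            drop = FALSE]
  ax <- lapply(grid_shape, seq_len)
  maps <- lapply(seq_len(k), function(i) {
    d2 <- outer(outer((ax[[1]] - centers[i, 1])^2,
                      (ax[[2]] - centers[i, 2])^2, "+"),
                (ax[[3]] - centers[i, 3])^2, "+")
    array(exp(-d2 / (2 * sigma_vox^2)), dim = grid_shape)
  })
  attr(maps, "centers") <- centers
  maps
}
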