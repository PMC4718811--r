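#' Convert a Gaussian FWHM to its standard deviation
#'
#' sigma = fwhm / sqrt(8 ln 2); a 12 mm FWHM corresponds to sigma
#' 5.0956 mm.
#'
#' @param fwhm full width at half maximum (mm), >= 0.
#' @return standard deviation in the same units.
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (any(fwhm < 0)) stop("fwhm must be non-negative")
  fwhm / sqrt(8 * log(2))
}

#' Scale the voxel grid by a constant factor
#'
#' Multiplies voxel spacing (and the origin, so that all coordinates live in
#' the scaled millimetre frame) by `factor`; voxel values and the grid shape
#' are unchanged. Small-animal PET volumes are conventionally scaled by 10 so
#' that human-calibrated tooling (smoothing kernels, cluster extents) applies.
#'
#' @param vol a `brain_volume`.
#' @param factor positive scale factor (10 for the rat convention).
#' @return A `brain_volume` in the scaled frame.
#' @export
scale_voxels <- function(vol, factor) {
  stopifnot(inherits(vol, "brain_volume"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0)
    stop("`factor` must be a single positive number")
  brain_volume(vol$values, vol$spacing * factor, vol$origin * factor)
}

# 1D convolution along one array axis with zero padding outside the grid,
# implemented as a banded matrix product on the unfolded array.
.convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[o + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

.gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Separable Gaussian smoothing of a brain volume
#'
#' Convolves with a normalized discrete Gaussian along each axis; the per-axis
#' sigma in voxels is `fwhm_mm / sqrt(8 ln 2)` divided by that axis's spacing,
#' so anisotropic grids are smoothed isotropically in mm. Values outside the
#' grid are treated as zero.
#'
#' @param vol a `brain_volume`.
#' @param fwhm_mm full width at half maximum in mm (in the volume's frame);
#'   0 returns the input unchanged.
#' @return A smoothed `brain_volume`.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "brain_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1 || !is.finite(fwhm_mm))
    stop("`fwhm_mm` must be a single finite number")
  if (fwhm_mm < 0) stop("`fwhm_mm` must be non-negative")
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  out <- vol$values
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / vol$spacing[axis]
    out <- .convolve_axis(out, .gaussian_kernel_1d(sigma_vox), axis)
  }
  brain_volume(out, vol$spacing, vol$origin)
}

#' Normalize a volume to its global in-mask uptake
#'
#' Divides every voxel by the arithmetic mean intensity over the brain mask,
#' so the in-mask mean of the result is exactly `reference` (default 1). This
#' removes global differences in injected dose and scanner sensitivity, the
#' standard proportional-scaling step before across-subject covariance
#' analysis.
#'
#' @param vol a `brain_volume`.
#' @param mask a `brain_mask` on the same grid.
#' @param reference target in-mask mean (default 1).
#' @return A normalized `brain_volume`.
#' @export
global_normalize <- function(vol, mask, reference = 1) {
  stopifnot(inherits(vol, "brain_volume"), inherits(mask, "brain_mask"))
  .check_same_grid(vol, mask, "volume and mask")
  g <- mean(vol$values[mask$values != 0])
  if (!is.finite(g) || g <= 0)
    stop(sprintf("global in-mask mean is %.4g; must be positive", g))
  brain_volume(vol$values * (reference / g), vol$spacing, vol$origin)
}

#' Preprocess a scan set: smooth then normalize to global uptake
#'
#' Applies, per subject, Gaussian smoothing at `fwhm_mm` followed by
#' global-uptake normalization over `mask` — the order used for FDG PET
#' covariance analysis.
#'
#' @param scans a `scan_set` (already in the scaled mm frame).
#' @param mask a `brain_mask`.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 12).
#' @param reference target in-mask mean (default 1).
#' @return A preprocessed `scan_set`.
#' @export
preprocess_scans <- function(scans, mask, fwhm_mm = 12, reference = 1) {
  map_scans(scans, function(v)
    global_normalize(gaussian_smooth(v, fwhm_mm), mask, reference))
}
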