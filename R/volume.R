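#' 3D brain volume with voxel spacing and a bregma-anchored origin
#'
#' The unit of all image math in this package. A `brain_volume` wraps a 3D
#' numeric array together with its voxel spacing (mm) and the millimetre
#' coordinate of the centre of voxel `[1,1,1]` relative to bregma. Axis
#' convention: x = medial-lateral (+ right), y = anterior-posterior
#' (+ anterior), z = dorsal-ventral stored as positive depth.
#'
#' @param values 3D numeric array of voxel intensities.
#' @param spacing numeric(3), voxel spacing in mm along x, y, z; all > 0.
#' @param origin numeric(3), mm coordinate of the centre of voxel `[1,1,1]`.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (any(!is.finite(values)))
    stop("volume contains non-finite values")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "brain_volume")
}

#' @export
dim.brain_volume <- function(x) dim(x$values)

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<brain_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 5), collapse = " x "),
              paste(signif(x$origin, 5), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Millimetre coordinates of voxel centres along each axis
#'
#' @param vol a `brain_volume`.
#' @return list of 3 numeric vectors (x, y, z voxel-centre coordinates, mm).
#' @export
voxel_coordinates <- function(vol) {
  stopifnot(inherits(vol, "brain_volume"))
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Binary brain mask on the same lattice as its volumes
#'
#' @param values 3D array coercible to logical; must mark at least one voxel.
#' @inheritParams brain_volume
#' @return A `brain_mask` (also a `brain_volume` with 0/1 values).
#' @export
brain_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  m <- brain_volume(array(as.numeric(values != 0), dim = dim(values)),
                    spacing, origin)
  if (sum(m$values) == 0) stop("brain mask is empty")
  class(m) <- c("brain_mask", class(m))
  m
}

.check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s have different grid shapes", what))
  if (max(abs(a$spacing - b$spacing)) > 1e-8)
    stop(sprintf("%s have different voxel spacings", what))
  invisible(TRUE)
}

.grid_affine <- function(spacing, origin) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(spacing)
  m[1:3, 4] <- origin
  m
}

#' Write a brain volume to a NIfTI-1 file
#'
#' Spacing is stored in pixdim and the bregma-anchored origin in the
#' qform/sform translation.
#'
#' @param vol a `brain_volume`.
#' @param path output filename (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "brain_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::`qform<-`(img, structure(.grid_affine(vol$spacing, vol$origin),
                                   code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a brain volume from a NIfTI-1 file
#'
#' @param path NIfTI filename.
#' @return A `brain_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  brain_volume(vals, spacing = RNifti::pixdim(img)[1:3], origin = xf[1:3, 4])
}

#' @rdname write_volume
#' @param mask a `brain_mask`.
#' @export
write_mask <- function(mask, path) write_volume(mask, path)

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  brain_mask(v$values != 0, v$spacing, v$origin)
}

#' Ordered collection of subject volumes forming one age group
#'
#' @param volumes list of `brain_volume`s on a shared grid.
#' @param subject_ids character vector, one per volume.
#' @param group single string, the age-group label.
#' @return A `scan_set`.
#' @export
scan_set <- function(volumes, subject_ids, group) {
  if (length(volumes) != length(subject_ids))
    stop("one subject ID per volume required")
  if (anyDuplicated(subject_ids))
    stop("subject IDs must be unique within a group")
  for (v in volumes) stopifnot(inherits(v, "brain_volume"))
  if (length(volumes) > 1)
    for (v in volumes[-1]) .check_same_grid(volumes[[1]], v)
  structure(list(volumes = volumes,
                 subject_ids = as.character(subject_ids),
                 group = as.character(group)[1]),
            class = "scan_set")
}

#' @export
length.scan_set <- function(x) length(x$volumes)

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> group '%s': %d subjects\n", x$group, length(x)))
  invisible(x)
}

#' Stack a scan set into a subjects x in-mask-voxels matrix
#'
#' @param scans a `scan_set`.
#' @param mask a `brain_mask` on the same grid (optional; all voxels if NULL).
#' @return numeric matrix with rownames = subject IDs.
#' @export
scan_matrix <- function(scans, mask = NULL) {
  stopifnot(inherits(scans, "scan_set"))
  keep <- if (is.null(mask)) {
    rep(TRUE, prod(dim(scans$volumes[[1]]$values)))
  } else {
    .check_same_grid(scans$volumes[[1]], mask, "volume and mask")
    as.vector(mask$values != 0)
  }
  out <- vapply(scans$volumes,
                function(v) as.vector(v$values)[keep],
                numeric(sum(keep)))
  out <- if (is.matrix(out)) t(out) else matrix(out, ncol = 1)
  rownames(out) <- scans$subject_ids
  out
}

#' Apply a volume-to-volume function to every subject in a scan set
#'
#' @param scans a `scan_set`.
#' @param f function taking and returning a `brain_volume`.
#' @param ... passed to `f`.
#' @return A `scan_set` with transformed volumes.
#' @export
map_scans <- function(scans, f, ...) {
  stopifnot(inherits(scans, "scan_set"))
  scan_set(lapply(scans$volumes, f, ...), scans$subject_ids, scans$group)
}
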