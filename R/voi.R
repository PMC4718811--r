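#' Default stereotaxic VOI table for the eight network nodes
#'
#' Spherical volume-of-interest centres for the rat metabolic-network nodes,
#' in Paxinos-Watson stereotaxic coordinates relative to bregma (ML, DV, AP in
#' mm): left/right dorsal hippocampus and medial prefrontal cortex on the
#' limbic/anterior-DMN component (IC1), retrosplenial cortex on the
#' posterior-DMN component (IC5), left/right motor cortex (IC8) and left/right
#' somatosensory cortex (IC9).
#'
#' @param scale multiplier applied to the coordinates; 10 (default) gives the
#'   x10-scaled frame in which all volumes of this package live.
#' @return data.frame with columns name, abbreviation, ml, dv, ap (mm in the
#'   scaled frame) and ic (parent component label).
#' @export
default_voi_table <- function(scale = 10) {
  tab <- data.frame(
    name = c("Left Hippocampus", "Right Hippocampus",
             "Medial Prefrontal Cortex", "Retrosplenial Cortex",
             "Left Motor Cortex", "Right Motor Cortex",
             "Left Somatosensory Cortex", "Right Somatosensory Cortex"),
    abbreviation = c("Hp_L", "Hp_R", "MedF", "Rsp",
                     "Mot_L", "Mot_R", "SS_L", "SS_R"),
    ml = c(-2.6, 2.6, 0.0, 0.0, -2.2, 2.2, -5.0, 5.0),
    dv = c(3.2, 3.2, 3.8, 1.8, 2.2, 2.2, 3.8, 3.8),
    ap = c(-3.2, -3.2, 4.0, -6.4, 2.2, 2.2, 0.6, 0.6),
    ic = c("IC1", "IC1", "IC1", "IC5", "IC8", "IC8", "IC9", "IC9"),
    stringsAsFactors = FALSE
  )
  tab$ml <- tab$ml * scale
  tab$dv <- tab$dv * scale
  tab$ap <- tab$ap * scale
  tab
}

#' Read a VOI table from TSV
#'
#' Expects columns name, abbreviation, ml, dv, ap (mm, already in the working
#' frame) and optionally ic.
#'
#' @param path TSV filename.
#' @return data.frame as from [default_voi_table()].
#' @export
read_voi_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "abbreviation", "ml", "dv", "ap")
  if (!all(need %in% names(tab)))
    stop("VOI table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_voi_table
#' @param tab a VOI table.
#' @export
write_voi_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a spherical VOI mask on a volume's grid
#'
#' Marks every voxel whose centre lies within `radius_mm` of the VOI centre,
#' measured in mm so anisotropic voxel spacing is respected. The centre is
#' given as stereotaxic (ML, DV, AP); grid axes are x = ML, y = AP, z = DV.
#'
#' @param center_mm numeric(3) c(ml, dv, ap) in the volume's mm frame.
#' @param radius_mm sphere radius in mm (> 0; 8 in the x10 frame by default).
#' @param vol a `brain_volume` supplying the grid geometry.
#' @return A `brain_mask`.
#' @export
make_voi_mask <- function(center_mm, radius_mm, vol) {
  stopifnot(inherits(vol, "brain_volume"))
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be positive")
  xyz <- c(center_mm[1], center_mm[3], center_mm[2]) # (ml, dv, ap) -> (x, y, z)
  cc <- voxel_coordinates(vol)
  lims <- vapply(1:3, function(a) range(cc[[a]]), numeric(2))
  if (any(xyz < lims[1, ] - 1e-9) || any(xyz > lims[2, ] + 1e-9))
    stop(sprintf("VOI centre (%.1f, %.1f, %.1f) mm lies outside the grid",
                 xyz[1], xyz[2], xyz[3]))
  d2 <- outer(outer((cc[[1]] - xyz[1])^2, (cc[[2]] - xyz[2])^2, "+"),
              (cc[[3]] - xyz[3])^2, "+")
  inside <- d2 <= radius_mm^2
  if (!any(inside))
    stop("VOI sphere contains no voxel centres; radius too small for grid")
  brain_mask(inside, vol$spacing, vol$origin)
}

#' Build all VOI masks from a coordinate table
#'
#' @param voi_table data.frame from [default_voi_table()] / [read_voi_table()].
#' @param vol a `brain_volume` supplying the grid.
#' @param radius_mm common sphere radius (default 8, x10 frame).
#' @return named list of `brain_mask`, one per table row.
#' @export
voi_masks <- function(voi_table, vol, radius_mm = 8) {
  masks <- lapply(seq_len(nrow(voi_table)), function(i)
    make_voi_mask(c(voi_table$ml[i], voi_table$dv[i], voi_table$ap[i]),
                  radius_mm, vol))
  names(masks) <- voi_table$abbreviation
  masks
}

#' Extract per-subject mean uptake in each VOI
#'
#' Entry (i, j) is the mean of subject i's volume over VOI mask j. Input scans
#' should already be globally normalized when the result is to be read as
#' normalized uptake.
#'
#' @param scans a `scan_set`.
#' @param masks named list of `brain_mask` from [voi_masks()].
#' @return A `voi_matrix`: subjects x VOIs numeric matrix with subject-ID
#'   rownames, VOI-abbreviation colnames and a `group` attribute.
#' @export
extract_voi_means <- function(scans, masks) {
  stopifnot(inherits(scans, "scan_set"), length(masks) >= 1)
  for (m in masks) .check_same_grid(scans$volumes[[1]], m, "volume and mask")
  idx <- lapply(masks, function(m) which(m$values != 0))
  out <- t(vapply(scans$volumes, function(v) {
    vals <- v$values
    vapply(idx, function(i) mean(vals[i]), numeric(1))
  }, numeric(length(masks))))
  dimnames(out) <- list(scans$subject_ids, names(masks))
  structure(out, group = scans$group, class = c("voi_matrix", "matrix"))
}
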