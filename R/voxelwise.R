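#' Voxelwise paired t contrast between two age groups
#'
#' Computes, at every in-mask voxel, the paired t statistic of within-subject
#' differences (group B minus group A) with `n_pairs - 1` degrees of freedom
#' and a two-sided p-value. Subjects are paired by ID; by default the
#' analysis is restricted to the subject-ID intersection of the two groups
#' (a longitudinal design may lose animals between time points). Voxels with
#' zero difference variance get t = 0, p = 1.
#'
#' @param group_a,group_b `scan_set`s on a shared grid.
#' @param mask a `brain_mask`; statistics are computed in-mask only.
#' @param pairing optional named character vector mapping group-A subject IDs
#'   to group-B subject IDs; default pairs identical IDs.
#' @param method `"paired"` (default) or `"welch"` for an unpaired
#'   unequal-variance fallback that uses all subjects.
#' @return A `stat_map`: list with 3D arrays `t` and `p` (NA outside the
#'   mask), `df`, `n_pairs`, `mask` and the contrast label.
#' @export
paired_t_map <- function(group_a, group_b, mask, pairing = NULL,
                         method = c("paired", "welch")) {
  stopifnot(inherits(group_a, "scan_set"), inherits(group_b, "scan_set"))
  method <- match.arg(method)
  .check_same_grid(group_a$volumes[[1]], group_b$volumes[[1]])
  ma <- scan_matrix(group_a, mask)
  mb <- scan_matrix(group_b, mask)
  if (method == "paired") {
    if (is.null(pairing)) {
      shared <- intersect(group_a$subject_ids, group_b$subject_ids)
      if (length(shared) == 0)
        stop("no shared subject IDs between groups; supply `pairing` or use method = \"welch\"")
      pairing <- stats::setNames(shared, shared)
    }
    if (!all(names(pairing) %in% group_a$subject_ids) ||
        !all(pairing %in% group_b$subject_ids))
      stop("`pairing` refers to unknown subject IDs")
    n <- length(pairing)
    if (n < 3) stop("paired t requires at least 3 pairs")
    d <- mb[pairing, , drop = FALSE] - ma[names(pairing), , drop = FALSE]
    mu <- colMeans(d)
    s <- sqrt(colSums(sweep(d, 2, mu)^2) / (n - 1))
    df <- n - 1
    tt <- ifelse(s > 0, mu / (s / sqrt(n)), 0)
    dfv <- rep(df, length(tt))
  } else {
    na <- nrow(ma); nb <- nrow(mb)
    if (na < 3 || nb < 3) stop("welch t requires at least 3 subjects per group")
    va <- apply(ma, 2, stats::var); vb <- apply(mb, 2, stats::var)
    se2 <- va / na + vb / nb
    tt <- ifelse(se2 > 0, (colMeans(mb) - colMeans(ma)) / sqrt(se2), 0)
    dfv <- ifelse(se2 > 0,
                  se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
                  na + nb - 2)
    df <- stats::median(dfv)
    n <- min(na, nb)
  }
  pp <- ifelse(tt == 0, 1, 2 * stats::pt(-abs(tt), dfv))
  shape <- dim(mask$values)
  tm <- array(NA_real_, shape); pm <- array(NA_real_, shape)
  keep <- mask$values != 0
  tm[keep] <- tt
  pm[keep] <- pp
  structure(list(t = tm, p = pm, df = df, n_pairs = n, mask = mask,
                 method = method,
                 contrast = sprintf("%s vs %s", group_b$group, group_a$group)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s (%s, df = %.1f, n = %d): peak |t| = %.2f\n",
              x$contrast, x$method, x$df, x$n_pairs,
              max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`: with ordered p-values p_(1) <= ... <=
#' p_(m), reject all hypotheses up to the largest i with p_(i) <= i*q/m.
#' Returned q-values are the usual monotone BH-adjusted p-values
#' (`stats::p.adjust` with method "BH"), which satisfy q >= p.
#'
#' @param p numeric vector of p-values in [0, 1] (may be empty).
#' @param q FDR level in (0, 1), default 0.05.
#' @return list with logical `reject` and numeric `qvalue`, both aligned
#'   with `p`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0)
    return(list(reject = logical(0), qvalue = numeric(0)))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)")
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(ok) > 0)
    reject[o[seq_len(max(ok))]] <- TRUE
  list(reject = reject, qvalue = stats::p.adjust(p, method = "BH"))
}

.neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & rowSums(g != 0) <= 2,
                 "26" = nz >= 1,
                 stop("`connectivity` must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected suprathreshold clusters and apply an extent filter
#'
#' Finds connected components of a binary 3D map under 6-, 18- or
#' 26-neighbourhood adjacency and discards components smaller than `extent`
#' voxels. When a t map and grid geometry are supplied, the cluster table
#' reports peak |t| location in mm and the effect sign.
#'
#' @param binary 3D logical/0-1 array of suprathreshold voxels.
#' @param connectivity 6 (faces), 18 (faces + edges, the usual neuroimaging
#'   default) or 26 (full 3x3x3).
#' @param extent minimum cluster size in voxels (default 100).
#' @param t_map optional 3D array of t values for peak reporting.
#' @param spacing,origin optional grid geometry for mm peak coordinates.
#' @return list with `labels` (integer 3D array, 0 = background) and `table`
#'   (data.frame: label, n_voxels, peak_x_mm, peak_y_mm, peak_z_mm, peak_t,
#'   direction), ordered by decreasing size.
#' @export
label_clusters <- function(binary, connectivity = 18, extent = 100,
                           t_map = NULL, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  if (!is.array(binary) || length(dim(binary)) != 3L)
    stop("`binary` must be a 3D array")
  offs <- .neighbor_offsets(connectivity)
  d <- dim(binary)
  fg <- which(binary != 0)
  labels <- array(0L, dim = d)
  if (length(fg) == 0)
    return(list(labels = labels, table = .empty_cluster_table()))
  inset <- array(FALSE, dim = d)
  inset[fg] <- TRUE
  lab <- 0L
  comps <- list()
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    members <- integer(0)
    while (length(queue) > 0) {
      members <- c(members, queue)
      coords <- arrayInd(queue, d)
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- coords + rep(offs[o, ], each = nrow(coords))
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
        lin <- lin[inset[lin] & labels[lin] == 0L]
        if (length(lin) > 0) {
          lin <- unique(lin)
          labels[lin] <- lab
          nxt <- c(nxt, lin)
        }
      }
      queue <- nxt
    }
    comps[[lab]] <- members
  }
  sizes <- lengths(comps)
  keep <- which(sizes >= extent)
  out_labels <- array(0L, dim = d)
  rows <- list()
  new_lab <- 0L
  for (ci in keep[order(sizes[keep], decreasing = TRUE)]) {
    new_lab <- new_lab + 1L
    vox <- comps[[ci]]
    out_labels[vox] <- new_lab
    if (!is.null(t_map)) {
      tv <- t_map[vox]
      pk <- vox[which.max(abs(tv))]
      pc <- arrayInd(pk, d)
      peak_t <- t_map[pk]
      peak_mm <- origin + (pc - 1) * spacing
    } else {
      peak_t <- NA_real_
      peak_mm <- rep(NA_real_, 3)
    }
    rows[[new_lab]] <- data.frame(
      label = new_lab, n_voxels = length(vox),
      peak_x_mm = peak_mm[1], peak_y_mm = peak_mm[2], peak_z_mm = peak_mm[3],
      peak_t = peak_t,
      direction = if (is.na(peak_t)) NA_character_ else
        if (peak_t >= 0) "increase" else "decrease",
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else .empty_cluster_table()
  list(labels = out_labels, table = tab)
}

.empty_cluster_table <- function() {
  data.frame(label = integer(0), n_voxels = integer(0),
             peak_x_mm = numeric(0), peak_y_mm = numeric(0),
             peak_z_mm = numeric(0), peak_t = numeric(0),
             direction = character(0), stringsAsFactors = FALSE)
}

#' Significant clusters of a voxelwise contrast
#'
#' Applies BH-FDR at level `q` to the in-mask p-values of a `stat_map`,
#' then labels connected suprathreshold clusters and filters them by extent.
#' Positive and negative effects are labelled separately so a cluster never
#' mixes directions.
#'
#' @param sm a `stat_map` from [paired_t_map()].
#' @param q FDR level (default 0.05).
#' @param extent minimum cluster size in voxels (default 100).
#' @param connectivity neighbourhood code (default 18).
#' @return list with `table` (signed cluster table), `q` (3D array of
#'   q-values) and `significant` (3D logical array after FDR, before extent).
#' @export
significant_clusters <- function(sm, q = 0.05, extent = 100,
                                 connectivity = 18) {
  stopifnot(inherits(sm, "stat_map"))
  keep <- sm$mask$values != 0
  fdr <- bh_fdr(sm$p[keep], q)
  shape <- dim(sm$mask$values)
  qarr <- array(NA_real_, shape)
  qarr[keep] <- fdr$qvalue
  sig <- array(FALSE, shape)
  sig[keep] <- fdr$reject
  sp <- sm$mask$spacing
  or <- sm$mask$origin
  pos <- label_clusters(sig & !is.na(sm$t) & sm$t > 0, connectivity, extent,
                        sm$t, sp, or)
  neg <- label_clusters(sig & !is.na(sm$t) & sm$t < 0, connectivity, extent,
                        sm$t, sp, or)
  tab <- rbind(pos$table, neg$table)
  if (nrow(tab) > 0) tab$label <- seq_len(nrow(tab))
  list(table = tab, q = qarr, significant = sig)
}
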