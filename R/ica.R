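#' Stack preprocessed scan sets into a pooled subjects x voxels data matrix
#'
#' All groups are pooled (spatial group ICA operates on the full cohort).
#'
#' @param scan_sets list of `scan_set`s.
#' @param mask a `brain_mask`.
#' @return numeric matrix, rownames `<group>:<subject>`.
#' @export
pool_data_matrix <- function(scan_sets, mask) {
  mats <- lapply(scan_sets, scan_matrix, mask = mask)
  for (i in seq_along(mats))
    rownames(mats[[i]]) <- paste(scan_sets[[i]]$group,
                                 rownames(mats[[i]]), sep = ":")
  do.call(rbind, mats)
}

# Eigendecomposition of the subject-by-subject covariance of voxelwise-centred
# data; the small dimension (subjects) makes this cheap even for large grids.
.subject_pca <- function(x) {
  if (nrow(x) < 3) stop("need at least 3 subjects")
  xc <- sweep(x, 2, colMeans(x))
  C <- tcrossprod(xc) / (ncol(xc) - 1)
  ev <- eigen(C, symmetric = TRUE)
  list(values = pmax(ev$values, 0), vectors = ev$vectors, centered = xc)
}

#' MDL estimate of the number of independent components
#'
#' Model-order selection on the eigenspectrum of the subject covariance
#' matrix using the minimum-description-length criterion: for each candidate
#' order k the code length balances the log ratio of geometric to arithmetic
#' mean of the trailing eigenvalues (sphericity of the noise subspace)
#' against a parameter-count penalty. The effective sample count is the
#' number of voxels times `sample_correction`, a factor (in (0, 1]) that
#' down-weights spatially smooth, non-independent voxels.
#'
#' @param x subjects x voxels data matrix.
#' @param sample_correction effective-sample fraction (default 1).
#' @return integer order estimate (>= 1, <= subjects - 1), with the full
#'   eigenspectrum and per-order MDL curve attached as attributes
#'   `eigenvalues` and `mdl`.
#' @export
estimate_ncomp <- function(x, sample_correction = 1) {
  stopifnot(is.matrix(x))
  if (sample_correction <= 0 || sample_correction > 1)
    stop("`sample_correction` must be in (0, 1]")
  pca <- .subject_pca(x)
  lam <- pca$values
  if (max(lam) <= 0) stop("data matrix has rank 0")
  # per-voxel centering loses one rank; keep only the non-null spectrum
  lam <- lam[lam > max(lam) * 1e-9]
  p <- length(lam)
  if (p < 3) stop("data matrix has rank < 3; cannot estimate model order")
  n_eff <- max(ncol(x) * sample_correction, p + 1)
  ks <- 0:(p - 2)
  mdl <- vapply(ks, function(k) {
    tail_lam <- lam[(k + 1):p]
    gm <- mean(log(tail_lam))
    am <- log(mean(tail_lam))
    -n_eff * (p - k) * (gm - am) + 0.5 * k * (2 * p - k) * log(n_eff)
  }, numeric(1))
  est <- ks[which.min(mdl)]
  est <- max(1L, min(as.integer(est), p - 1L))
  attr(est, "eigenvalues") <- pca$values
  attr(est, "mdl") <- stats::setNames(mdl, ks)
  est
}

# PCA whitening to k dimensions. Returns the k x voxels whitened matrix with
# identity covariance, plus the dewhitening map back to subject space.
.whiten <- function(x, k) {
  pca <- .subject_pca(x)
  if (k > sum(pca$values > max(pca$values) * 1e-10))
    stop(sprintf("k = %d exceeds the rank of the data", k))
  E <- pca$vectors[, seq_len(k), drop = FALSE]
  lam <- pca$values[seq_len(k)]
  z <- (t(E) / sqrt(lam)) %*% pca$centered
  list(z = z, dewhiten = E %*% diag(sqrt(lam), k),
       centered = pca$centered,
       var_retained = sum(lam) / sum(pca$values))
}

# Natural-gradient infomax with a logistic nonlinearity on whitened data.
# Full-batch updates (deterministic given the seeded initialization); the
# learning rate is halved and the step retried when the weights blow up or
# the update norm jumps, which anneals automatically near convergence.
.infomax_unmix <- function(z, seed, lr = 0.05, max_iter = 500, tol = 1e-6) {
  k <- nrow(z); n <- ncol(z)
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
  I <- diag(k)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    u <- W %*% z
    y <- 1 / (1 + exp(-u))
    G <- (I + tcrossprod(1 - 2 * y, u) / n) %*% W
    W_new <- W + lr * G
    if (!all(is.finite(W_new)) || max(abs(W_new)) > 1e6) {
      lr <- lr / 2
      if (lr < 1e-10) break
      next
    }
    delta <- sqrt(sum((lr * G)^2) / sum(W^2))
    W <- W_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(W = W, iterations = it, converged = converged, lr_final = lr)
}

#' Spatial group ICA by PCA whitening and infomax unmixing
#'
#' Centres the pooled subjects x voxels matrix per voxel, whitens it to `k`
#' principal dimensions, and unmixes with the infomax algorithm (natural
#' gradient, logistic nonlinearity), which maximizes output entropy and
#' thereby minimizes mutual information between the spatial sources. Each
#' component map is sign-aligned to positive skewness and z-scored over
#' in-mask voxels; the mixing matrix maps z-scored maps back to the centred
#' data.
#'
#' @param x subjects x in-mask-voxels data matrix (e.g. from
#'   [pool_data_matrix()]).
#' @param k number of components (<= rank of `x`); e.g. from
#'   [estimate_ncomp()].
#' @param seed integer seed for the unmixing initialization and visiting
#'   order; identical data + seed give identical maps.
#' @param max_iter,tol,learning_rate infomax stopping controls.
#' @return A `component_set`: list with `maps` (k x voxels, z-scored rows),
#'   `mixing` (subjects x k), `order` (components by decreasing explained
#'   mixing variance), `var_retained` (PCA variance fraction kept),
#'   `converged`, `iterations`.
#' @export
infomax_ica <- function(x, k, seed = 1L, max_iter = 500, tol = 1e-6,
                        learning_rate = 0.05) {
  stopifnot(is.matrix(x))
  if (k < 1) stop("`k` must be >= 1")
  wh <- .whiten(x, k)
  fit <- .infomax_unmix(wh$z, seed = seed, lr = learning_rate,
                        max_iter = max_iter, tol = tol)
  if (!fit$converged)
    warning(sprintf("infomax did not reach tol %.1e in %d iterations", tol,
                    fit$iterations))
  s <- fit$W %*% wh$z
  a <- wh$dewhiten %*% solve(fit$W)
  flip <- ifelse(apply(s, 1, function(r) mean((r - mean(r))^3)) < 0, -1, 1)
  s <- s * flip
  a <- sweep(a, 2, flip, "*")
  mu <- rowMeans(s)
  sd_ <- apply(s, 1, stats::sd)
  maps <- (s - mu) / sd_
  mixing <- sweep(a, 2, sd_, "*")
  offsets <- as.vector(a %*% mu)
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  maps <- maps[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  rownames(maps) <- colnames(mixing) <- sprintf("IC%d", seq_len(k))
  rownames(mixing) <- rownames(x) %||% sprintf("s%d", seq_len(nrow(x)))
  structure(list(maps = maps, mixing = mixing, offsets = offsets,
                 order = ord, var_retained = wh$var_retained,
                 converged = fit$converged, iterations = fit$iterations,
                 seed = seed),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components, %d subjects, %.1f%% variance retained%s\n",
              nrow(x$maps), nrow(x$mixing), 100 * x$var_retained,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Threshold a z-scored component map
#'
#' @param map numeric vector or array of z values.
#' @param z threshold (default 1.5, the usual display threshold).
#' @return logical object of the same shape, TRUE where map > z.
#' @export
threshold_component <- function(map, z = 1.5) map > z

#' Match estimated components to reference maps
#'
#' Greedy assignment maximizing |spatial Pearson correlation| between
#' estimated and reference maps, with sign alignment (ICA maps have
#' arbitrary sign).
#'
#' @param estimated k x voxels matrix of estimated maps (or `component_set`).
#' @param reference m x voxels matrix of reference maps on the same voxel set.
#' @return data.frame with columns `estimated`, `reference`, `r` (signed
#'   correlation after sign alignment, so r >= 0 means aligned) and
#'   `abs_r`.
#' @export
match_components <- function(estimated, reference) {
  if (inherits(estimated, "component_set")) estimated <- estimated$maps
  if (!is.matrix(reference)) reference <- matrix(reference, nrow = 1)
  if (ncol(estimated) != ncol(reference))
    stop("estimated and reference maps are on different voxel grids")
  cc <- stats::cor(t(estimated), t(reference))
  k <- nrow(estimated); m <- nrow(reference)
  rows <- list()
  ac <- abs(cc)
  for (step in seq_len(min(k, m))) {
    ij <- arrayInd(which.max(ac), dim(ac))
    i <- ij[1]; j <- ij[2]
    rows[[step]] <- data.frame(estimated = i, reference = j,
                               r = cc[i, j], abs_r = abs(cc[i, j]))
    ac[i, ] <- -Inf
    ac[, j] <- -Inf
  }
  out <- do.call(rbind, rows)
  out[order(out$reference), , drop = FALSE]
}

#' Write a component set as a 4D NIfTI plus mixing TSV
#'
#' @param comps a `component_set`.
#' @param mask the `brain_mask` whose in-mask voxels the maps live on.
#' @param path_maps output NIfTI filename (4D, one volume per component).
#' @param path_mixing output TSV filename for the mixing matrix.
#' @return invisibly, `path_maps`.
#' @export
write_components <- function(comps, mask, path_maps, path_mixing) {
  stopifnot(inherits(comps, "component_set"), inherits(mask, "brain_mask"))
  keep <- mask$values != 0
  k <- nrow(comps$maps)
  arr <- array(0, dim = c(dim(mask$values), k))
  for (i in seq_len(k)) {
    v <- array(0, dim = dim(mask$values))
    v[keep] <- comps$maps[i, ]
    arr[, , , i] <- v
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(mask$spacing, 1)
  RNifti::writeNifti(img, path_maps)
  utils::write.table(data.frame(subject = rownames(comps$mixing),
                                comps$mixing, check.names = FALSE),
                     path_mixing, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path_maps)
}
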