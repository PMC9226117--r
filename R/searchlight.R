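#' Volume grid with brain and gray-matter masks
#'
#' @param dims Integer triple of volume dimensions.
#' @param voxel_size Voxel edge length in mm (isotropic or length 3).
#' @param brain_mask,graymatter_mask Logical arrays matching `dims`; gray
#'   matter must be nested inside the brain mask.
#' @return A `volume_grid` list.
#' @export
volume_grid <- function(dims, voxel_size = 1.5, brain_mask,
                        graymatter_mask) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3)
  if (!all(dim(brain_mask) == dims) || !all(dim(graymatter_mask) == dims)) {
    stop("masks must match the volume dimensions", call. = FALSE)
  }
  if (any(graymatter_mask & !brain_mask)) {
    stop("gray-matter mask must be nested inside the brain mask", call. = FALSE)
  }
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  structure(list(dims = dims, voxel_size = voxel_size,
                 brain_mask = brain_mask, graymatter_mask = graymatter_mask),
            class = "volume_grid")
}

#' Voxels inside a search sphere
#'
#' All voxels whose Euclidean offset from the center is at most `radius`
#' (voxel units), clipped to the volume and intersected with the brain
#' mask. Gray-matter filtering is the caller's responsibility.
#'
#' @param center Integer triple (1-based voxel indices); must lie inside
#'   the brain mask.
#' @param radius Sphere radius in voxels.
#' @param grid A [volume_grid()].
#' @return Integer matrix with one row per voxel (columns x, y, z).
#' @export
sphere_indices <- function(center, radius, grid) {
  center <- as.integer(center)
  if (any(center < 1) || any(center > grid$dims)) {
    stop("center outside volume", call. = FALSE)
  }
  if (!grid$brain_mask[center[1], center[2], center[3]]) {
    stop("center outside brain mask", call. = FALSE)
  }
  r <- floor(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2, ]
  vox <- cbind(center[1] + offs$dx, center[2] + offs$dy, center[3] + offs$dz)
  inside <- vox[, 1] >= 1 & vox[, 1] <= grid$dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= grid$dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= grid$dims[3]
  vox <- vox[inside, , drop = FALSE]
  keep <- grid$brain_mask[vox]
  colnames(vox) <- c("x", "y", "z")
  vox[keep, , drop = FALSE]
}

# The three searchlight models on a pair table: virtual time on
# same-sequence pairs, on different-sequence pairs, and the membership x
# virtual-time interaction over all pairs. Returns the model list the C++
# engine consumes (X includes the intercept; rows are 1-based pair
# indices; focal is the 1-based column of X).
searchlight_models <- function(pairs) {
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  same_rows <- which(pairs$same_sequence)
  diff_rows <- which(!pairs$same_sequence)
  vd_all <- zs(pairs$virtual_distance)
  seq_dev <- ifelse(pairs$same_sequence, 0.5, -0.5)
  list(
    same = list(
      X = cbind(1, zs(pairs$virtual_distance[same_rows])),
      rows = same_rows, focal = 2L
    ),
    different = list(
      X = cbind(1, zs(pairs$virtual_distance[diff_rows])),
      rows = diff_rows, focal = 2L
    ),
    interaction = list(
      X = cbind(1, vd_all, seq_dev, vd_all * seq_dev),
      rows = seq_len(nrow(pairs)), focal = 4L
    )
  )
}

#' Whole-volume searchlight RSA
#'
#' For every brain voxel, gray-matter voxels within a sphere of the given
#' radius are collected; spheres with 25 or fewer gray-matter voxels are
#' discarded. For the remaining spheres, pattern-similarity change is
#' computed from the sphere's voxels and three linear models are fitted
#' (virtual time for same-sequence pairs, for different-sequence pairs,
#' and the membership-by-virtual-time interaction over all pairs); each
#' model's focal t-value is stored at the center voxel.
#'
#' @param pre,post Pattern matrices, `(n_events * n_miniblocks) x V_brain`
#'   with rows ordered event-major (mini-block fastest), columns matching
#'   the brain voxels of `grid` in linear-index order.
#' @param grid A [volume_grid()].
#' @param pairs Pair table of the subject's design.
#' @param radius Sphere radius in voxels.
#' @param min_gray Spheres with at most this many gray-matter voxels are
#'   skipped.
#' @param n_events,n_miniblocks Pattern layout.
#' @return A list of three t-maps (`same`, `different`, `interaction`),
#'   each an array of `grid$dims` with `NaN` outside valid centers.
#' @export
run_searchlight <- function(pre, post, grid, pairs, radius = 3,
                            min_gray = 25L, n_events = 20L,
                            n_miniblocks = 10L) {
  brain_idx <- which(grid$brain_mask)
  if (ncol(pre) != length(brain_idx) || ncol(post) != length(brain_idx)) {
    stop("pattern matrices must have one column per brain voxel",
         call. = FALSE)
  }
  coords <- which(grid$brain_mask, arr.ind = TRUE)
  storage.mode(coords) <- "integer"
  gray <- grid$graymatter_mask[brain_idx]
  models <- searchlight_models(pairs)
  tmat <- cpp_searchlight(pre, post, coords, gray, grid$dims, n_events,
                          n_miniblocks, radius, as.integer(min_gray), models)
  if (all(!is.finite(tmat))) stop("no valid searchlight centers", call. = FALSE)
  out <- lapply(seq_along(models), function(k) {
    vol <- array(NaN, dim = grid$dims)
    vol[brain_idx] <- tmat[, k]
    vol
  })
  names(out) <- names(models)
  out
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates cluster extent and height over thresholds
#' (`sum e(h)^E h^H dh`, 100 steps up to the map maximum,
#' 26-connectivity). Only the positive direction is enhanced: voxels at or
#' below zero map to zero. `NaN` voxels are ignored and stay `NaN`.
#'
#' @param map 3-d statistic array.
#' @param h,e Height and extent exponents (defaults 2 and 0.5).
#' @param n_steps Number of integration steps.
#' @return The TFCE-transformed array.
#' @export
tfce_transform <- function(map, h = 2, e = 0.5, n_steps = 100L) {
  dims <- dim(map)
  array(cpp_tfce(as.numeric(map), as.integer(dims), h, e,
                 as.integer(n_steps)), dim = dims)
}

# NaN-aware 1-d Gaussian convolution along one axis of a 3-d array.
convolve_axis <- function(vol, kernel, axis) {
  dims <- dim(vol)
  r <- (length(kernel) - 1) / 2
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  d <- dim(v)
  m <- matrix(v, nrow = d[1])
  out <- matrix(0, nrow = d[1], ncol = ncol(m))
  for (k in seq_along(kernel)) {
    off <- k - 1 - r
    src <- seq_len(d[1]) + off
    ok <- src >= 1 & src <= d[1]
    out[ok, ] <- out[ok, ] + kernel[k] * m[src[ok], ]
  }
  res <- array(out, dim = d)
  aperm(res, order(perm))
}

#' Gaussian smoothing of a statistic map
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis, converted from mm to voxel units via the grid's voxel size.
#' Invalid (`NaN`) voxels are excluded and the kernel weights are
#' renormalized over the valid support, so valid values never bleed into
#' or from undefined regions.
#'
#' @param map 3-d array (may contain `NaN`).
#' @param fwhm_mm Full width at half maximum, mm.
#' @param grid A [volume_grid()].
#' @return The smoothed array; `NaN` voxels stay `NaN`.
#' @export
smooth_map <- function(map, fwhm_mm, grid) {
  if (fwhm_mm <= 0) stop("fwhm must be positive", call. = FALSE)
  valid <- is.finite(map)
  num <- ifelse(valid, map, 0)
  den <- ifelse(valid, 1, 0)
  for (axis in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size[axis]
    r <- max(1L, ceiling(3 * sigma))
    kernel <- stats::dnorm(-r:r, sd = sigma)
    kernel <- kernel / sum(kernel)
    num <- convolve_axis(num, kernel, axis)
    den <- convolve_axis(den, kernel, axis)
  }
  out <- num / den
  out[!valid] <- NaN
  out
}

#' Group-level searchlight test with TFCE and small-volume correction
#'
#' Voxelwise one-sample t-test across subjects, transformed with
#' threshold-free cluster enhancement (height exponent H, extent exponent
#' E, 100 integration steps, 26-connectivity; positive and negative
#' directions enhanced separately and combined for a two-sided test).
#' Family-wise error within the small-volume-correction mask is controlled
#' with the max-TFCE distribution over random sign-flips; voxelwise
#' uncorrected permutation p-values are also returned.
#'
#' @param maps List of per-subject 3-d t-maps (aligned; `NaN` where
#'   invalid).
#' @param svc_mask Logical array: the small-volume correction mask.
#' @param n_flips Number of sign-flips.
#' @param seed Integer seed.
#' @param tfce_h,tfce_e,tfce_steps TFCE parameters (defaults H = 2,
#'   E = 0.5, 100 steps).
#' @param grid Optional [volume_grid()] (for dimension checking).
#' @return A list of arrays: `t`, `tfce`, `p_corrected` (inside the mask),
#'   `p_uncorrected`, plus `n_subjects` and `n_flips`.
#' @export
group_map_test <- function(maps, svc_mask, n_flips = 10000L, seed = 1L,
                           tfce_h = 2, tfce_e = 0.5, tfce_steps = 100L,
                           grid = NULL) {
  dims <- dim(maps[[1]])
  if (sum(svc_mask) == 0) stop("empty small-volume correction mask",
                               call. = FALSE)
  if (length(maps) < 8) {
    warning("fewer than 8 subjects: sign-flip null is very coarse")
  }
  S <- length(maps)
  M <- do.call(rbind, lapply(maps, as.vector))
  res <- with_seed_(seed, {
    cpp_group_map_test(M, as.integer(dims), as.logical(svc_mask),
                       tfce_h, tfce_e, as.integer(tfce_steps),
                       as.integer(n_flips))
  })
  out <- lapply(res, function(v) array(v, dim = dims))
  out$n_subjects <- S
  out$n_flips <- n_flips
  out
}

#' Cluster-based region of interest around the group peak
#'
#' Thresholds the uncorrected p-map inside the small-volume mask and
#' returns the 26-connected component that contains the peak voxel
#' (maximum absolute t).
#'
#' @param t_map Group t-map array.
#' @param p_map Uncorrected p-map array.
#' @param threshold_p Uncorrected threshold (the study used 0.01, with
#'   0.001 as a robustness check).
#' @param svc_mask Logical array.
#' @return A logical array (the ROI); attribute `empty` is `TRUE` when no
#'   voxel survives the threshold.
#' @export
peak_roi_from_cluster <- function(t_map, p_map, threshold_p = 0.01,
                                  svc_mask) {
  dims <- dim(t_map)
  supra <- is.finite(p_map) & (p_map < threshold_p) & svc_mask
  if (!any(supra)) {
    out <- array(FALSE, dim = dims)
    attr(out, "empty") <- TRUE
    return(out)
  }
  labels <- array(cpp_components(as.logical(supra), as.integer(dims)),
                  dim = dims)
  tv <- abs(t_map)
  tv[!supra] <- -Inf
  peak <- which.max(tv)
  roi <- labels == labels[peak]
  attr(roi, "empty") <- FALSE
  attr(roi, "peak") <- arrayInd(peak, dims)
  roi
}

#' Peak table of a group searchlight result
#'
#' Local summary of the strongest voxels of a contrast: voxel indices,
#' mm coordinates, t, TFCE value, and corrected p, sorted by |t|.
#'
#' @param result A [group_map_test()] result.
#' @param grid A [volume_grid()] (for mm coordinates).
#' @param n_peaks Number of rows to return.
#' @param mask Optional logical array restricting the search.
#' @return A tibble with one row per peak voxel.
#' @export
peaks_table <- function(result, grid, n_peaks = 10L, mask = NULL) {
  tv <- result$t
  ok <- is.finite(tv)
  if (!is.null(mask)) ok <- ok & mask
  idx <- which(ok)
  idx <- idx[order(-abs(tv[idx]))]
  idx <- utils::head(idx, n_peaks)
  coords <- arrayInd(idx, dim(tv))
  tibble::tibble(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    x_mm = (coords[, 1] - 1) * grid$voxel_size[1],
    y_mm = (coords[, 2] - 1) * grid$voxel_size[2],
    z_mm = (coords[, 3] - 1) * grid$voxel_size[3],
    t = tv[idx],
    tfce = result$tfce[idx],
    p_corrected = result$p_corrected[idx],
    p_uncorrected = result$p_uncorrected[idx]
  )
}

#' Per-subject peak t-values for brain-behavior analysis
#'
#' Extracts, for each subject, the t-value at the group-level peak voxel
#' of a searchlight contrast within a mask.
#'
#' @param maps List of per-subject t-map arrays.
#' @param group_t Group t-map array.
#' @param mask Logical array restricting the peak search.
#' @return A tibble: `subject_id`, `peak_t`; the peak voxel index is
#'   attached as an attribute.
#' @export
peak_subject_tvalues <- function(maps, group_t, mask) {
  tv <- abs(group_t)
  tv[!mask | !is.finite(group_t)] <- -Inf
  peak <- which.max(tv)
  out <- tibble::tibble(
    subject_id = seq_along(maps),
    peak_t = vapply(maps, function(m) m[peak], numeric(1))
  )
  attr(out, "peak") <- arrayInd(peak, dim(group_t))
  out
}
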