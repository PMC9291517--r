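# Volume preprocessing: isotropic resampling, rigid alignment to a common
# grid and centroid, and exact signed Euclidean distance transforms.
#
# Sign convention (fixed and asserted in tests): negative inside, positive
# outside; distance is measured to the nearest opposite-phase voxel center
# minus half a voxel, i.e. to the voxel-face interface. No size normalization
# is ever applied: ventricular dilation is signal, not nuisance.

#' Resample a segmentation mask to isotropic spacing
#'
#' Nearest-neighbor sampling of the binary mask onto an isotropic grid
#' covering the same physical extent; foreground volume is preserved to
#' within a few percent for smooth shapes.
#'
#' @param mask an `rv_mask`.
#' @param target_spacing isotropic spacing (mm).
#' @return an isotropic `rv_mask`.
#' @export
resample_isotropic <- function(mask, target_spacing = 1.5) {
  stopifnot(inherits(mask, "rv_mask"))
  if (target_spacing <= 0) abort("target_spacing must be positive")
  if (sum(mask$voxels) == 0) abort("mask has no foreground voxels")
  if (mask_is_isotropic(mask) && abs(mask$spacing[1] - target_spacing) < 1e-9) {
    return(mask)
  }
  old_dims <- dim(mask$voxels)
  extent <- old_dims * mask$spacing
  new_dims <- pmax(as.integer(ceiling(extent / target_spacing)), 1L)
  # sample new voxel centers in the old grid (nearest neighbor)
  src_idx <- lapply(1:3, function(d) {
    centers <- mask$origin[d] + (seq_len(new_dims[d]) - 1) * target_spacing +
      (target_spacing - mask$spacing[d]) / 2
    i <- round((centers - mask$origin[d]) / mask$spacing[d]) + 1
    pmin(pmax(i, 1), old_dims[d])
  })
  vox <- mask$voxels[src_idx[[1]], src_idx[[2]], src_idx[[3]], drop = FALSE]
  new_origin <- mask$origin + (target_spacing - mask$spacing) / 2
  new_mask(vox, target_spacing, new_origin, mask$subject_id)
}

# principal-axis rotation with deterministic sign disambiguation: axes ordered
# by decreasing variance, each column's sign chosen so the third moment of the
# projected coordinates is non-negative; handedness fixed last.
principal_rotation <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  R <- ev$vectors
  for (d in 1:3) {
    m3 <- mean((cc %*% R[, d])^3)
    if (m3 < 0) R[, d] <- -R[, d]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

#' Rigidly align a set of masks to a common grid and centroid
#'
#' All masks are padded to identical dimensions and shifted by whole voxels so
#' every foreground centroid lies at the grid center (within half a voxel);
#' the sub-voxel remainder is absorbed into each mask's origin, so centroids
#' coincide exactly in world coordinates. By default the alignment is
#' translation-only, matching the constraint of identical dimensions and
#' centroids; set `rotate = TRUE` to additionally align principal axes (signs
#' disambiguated by third moments).
#'
#' @param masks list of isotropic `rv_mask` objects at a common spacing.
#' @param rotate align principal axes as well (default `FALSE`).
#' @param pad extra margin in voxels around the cohort-wide bounding box.
#' @return list of aligned `rv_mask` objects on one shared grid whose center
#'   voxel is world coordinate (0, 0, 0).
#' @export
align_rigid <- function(masks, rotate = FALSE, pad = 4L) {
  if (length(masks) < 1) abort("need at least one mask")
  stopifnot(all(vapply(masks, inherits, logical(1), "rv_mask")))
  sp <- vapply(masks, function(m) m$spacing[1], numeric(1))
  if (!all(vapply(masks, mask_is_isotropic, logical(1))) ||
      diff(range(sp)) > 1e-9) {
    abort("all masks must be isotropic at the same spacing; resample first")
  }
  spacing <- sp[1]

  if (rotate) {
    masks <- lapply(masks, function(m) {
      idx <- which(m$voxels != 0, arr.ind = TRUE)
      coords <- sweep((idx - 1) * spacing, 2, -m$origin, "-")
      R <- principal_rotation(coords)
      ctr <- mask_centroid(m)
      dims <- dim(m$voxels)
      ax <- lapply(1:3, function(d) voxel_centers_axis(dims[d], spacing, m$origin[d]))
      grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
      # canonical-frame grid point q maps to source point ctr + R q
      src <- sweep(sweep(grid, 2, ctr) %*% t(R), 2, ctr, "+")
      i <- round(sweep(src, 2, m$origin) / spacing) + 1
      ok <- i[, 1] >= 1 & i[, 1] <= dims[1] & i[, 2] >= 1 & i[, 2] <= dims[2] &
        i[, 3] >= 1 & i[, 3] <= dims[3]
      vals <- integer(nrow(i))
      vals[ok] <- m$voxels[i[ok, , drop = FALSE]]
      new_mask(array(vals, dim = dims), spacing, m$origin, m$subject_id)
    })
  }

  # half-extent of each mask's foreground about its centroid, in voxels
  half <- vapply(masks, function(m) {
    idx <- which(m$voxels != 0, arr.ind = TRUE)
    cv <- colMeans(idx)
    max(apply(abs(sweep(idx, 2, cv)), 2, max))
  }, numeric(1))
  half_n <- ceiling(max(half)) + pad
  n <- 2L * as.integer(half_n) + 1L
  origin <- rep(-(n - 1) / 2 * spacing, 3)
  center_vox <- (n + 1) / 2

  lapply(masks, function(m) {
    idx <- which(m$voxels != 0, arr.ind = TRUE)
    cv <- colMeans(idx)
    shift <- round(center_vox - cv)
    out <- array(0L, dim = c(n, n, n))
    ni <- sweep(idx, 2, shift, "+")
    keep <- ni[, 1] >= 1 & ni[, 1] <= n & ni[, 2] >= 1 & ni[, 2] <= n &
      ni[, 3] >= 1 & ni[, 3] <= n
    out[ni[keep, , drop = FALSE]] <- 1L
    # voxels are shifted by whole steps; the sub-voxel remainder moves into
    # the origin so every foreground centroid sits exactly at world (0,0,0)
    cv_new <- colMeans(which(out != 0, arr.ind = TRUE))
    new_mask(out, spacing, -(cv_new - 1) * spacing, m$subject_id)
  })
}

#' Signed Euclidean distance transform of a segmentation mask
#'
#' Exact Euclidean distance (Felzenszwalb-Huttenlocher transform), negative
#' strictly inside and positive strictly outside, measured to the nearest
#' opposite-phase voxel center minus half a voxel (the voxel-face interface
#' convention), so the zero level set tracks the mask boundary and the
#' gradient magnitude is ~1 away from the medial axis.
#'
#' @param mask an isotropic `rv_mask` with both phases present.
#' @return an `rv_dt`: list with `values` (3D array, mm), `spacing`, `origin`.
#' @export
signed_distance_transform <- function(mask) {
  stopifnot(inherits(mask, "rv_mask"))
  if (!mask_is_isotropic(mask)) abort("mask must be isotropic; resample first")
  nf <- sum(mask$voxels)
  if (nf == 0) abort("mask is all background; distance transform undefined")
  if (nf == length(mask$voxels)) abort("mask is all foreground; distance transform undefined")
  dims <- dim(mask$voxels)
  spacing <- mask$spacing[1]
  fg <- mask$voxels != 0
  d_out <- sqrt(edt3d_sq(as.vector(fg), dims[1], dims[2], dims[3]))
  d_in <- sqrt(edt3d_sq(as.vector(!fg), dims[1], dims[2], dims[3]))
  vals <- ifelse(as.vector(fg), -(d_in - 0.5), d_out - 0.5) * spacing
  structure(list(values = array(vals, dim = dims), spacing = spacing,
                 origin = mask$origin, subject_id = mask$subject_id),
            class = "rv_dt")
}

#' @export
print.rv_dt <- function(x, ...) {
  cat(sprintf("<rv_dt> %s: %s grid at %.2f mm, range [%.1f, %.1f] mm\n",
              x$subject_id %||% "?", paste(dim(x$values), collapse = "x"),
              x$spacing, min(x$values), max(x$values)))
  invisible(x)
}

#' Preprocess a list of masks into aligned distance transforms
#'
#' Convenience wrapper: isotropic resampling, rigid alignment, signed
#' distance transform, in that order.
#'
#' @param masks list of `rv_mask`.
#' @param spacing target isotropic spacing (mm).
#' @param rotate passed to [align_rigid()].
#' @return list of `rv_dt` on a shared grid.
#' @export
preprocess_masks <- function(masks, spacing = 1.5, rotate = FALSE) {
  masks <- lapply(masks, resample_isotropic, target_spacing = spacing)
  masks <- align_rigid(masks, rotate = rotate)
  lapply(masks, signed_distance_transform)
}
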