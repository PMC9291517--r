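# Internal geometry and array helpers shared across modules.

# wrap angles to [-pi, pi)
wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# world coordinate of voxel centers: origin refers to the center of voxel (1,1,1)
voxel_centers_axis <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

#' Trilinear interpolation of a 3D scalar field at arbitrary points
#'
#' @param values 3D array sampled at voxel centers.
#' @param spacing,origin grid geometry (isotropic spacing, mm; origin = center
#'   of voxel `[1,1,1]`).
#' @param pts N x 3 matrix of world coordinates (mm). Points are clamped to the
#'   grid interior.
#' @return numeric vector of length N.
#' @keywords internal
interp3 <- function(values, spacing, origin, pts) {
  dims <- dim(values)
  # continuous (1-based) voxel coordinates
  u <- sweep(pts, 2, origin, "-") / spacing + 1
  for (d in 1:3) u[, d] <- pmin(pmax(u[, d], 1), dims[d] - 1e-9)
  i0 <- pmin(floor(u), matrix(rep(dims - 1L, each = nrow(u)), ncol = 3))
  fr <- u - i0
  idx <- function(a, b, c) {
    values[cbind(i0[, 1] + a, i0[, 2] + b, i0[, 3] + c)]
  }
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  c00 <- idx(0, 0, 0) * (1 - fx) + idx(1, 0, 0) * fx
  c10 <- idx(0, 1, 0) * (1 - fx) + idx(1, 1, 0) * fx
  c01 <- idx(0, 0, 1) * (1 - fx) + idx(1, 0, 1) * fx
  c11 <- idx(0, 1, 1) * (1 - fx) + idx(1, 1, 1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# central-difference gradient of an interpolated field at points (N x 3 -> N x 3)
interp3_grad <- function(values, spacing, origin, pts, h = spacing / 2) {
  g <- matrix(0, nrow(pts), 3)
  for (d in 1:3) {
    e <- matrix(0, nrow(pts), 3); e[, d] <- h
    g[, d] <- (interp3(values, spacing, origin, pts + e) -
                 interp3(values, spacing, origin, pts - e)) / (2 * h)
  }
  g
}

#' Greedy farthest-point subsampling
#'
#' Deterministic: starts from `start` and repeatedly adds the point farthest
#' from the selected set.
#'
#' @param pts N x 3 matrix.
#' @param m number of points to select.
#' @param start index of the first selected point.
#' @return integer vector of m indices.
#' @keywords internal
farthest_point_indices <- function(pts, m, start = 1L) {
  n <- nrow(pts)
  if (m > n) abort(sprintf("requested %d points but only %d grid samples available", m, n))
  sel <- integer(m)
  sel[1] <- start
  d2 <- rowSums(sweep(pts, 2, pts[start, ], "-")^2)
  if (m > 1) for (i in 2:m) {
    nxt <- which.max(d2)
    sel[i] <- nxt
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[nxt, ], "-")^2))
  }
  sel
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
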