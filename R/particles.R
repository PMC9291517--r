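# Particle systems: ordered correspondence points across a cohort, their
# text-file round trip, surface projection, and the ground-truth bypass.

#' Construct a particle system
#'
#' @param points K x M x 3 array of particle coordinates (mm), index j in the
#'   second dimension referring to the corresponding location on every subject.
#' @param subject_ids character vector of length K.
#' @return an `rv_particles`.
#' @export
new_particle_system <- function(points, subject_ids = NULL) {
  stopifnot(length(dim(points)) == 3, dim(points)[3] == 3)
  K <- dim(points)[1]
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(K))
  structure(list(points = points, subject_ids = subject_ids, M = dim(points)[2]),
            class = "rv_particles")
}

#' @export
print.rv_particles <- function(x, ...) {
  cat(sprintf("<rv_particles> %d subjects x %d particles\n",
              dim(x$points)[1], x$M))
  invisible(x)
}

#' Tidy a particle system into a long tibble
#'
#' @param x an `rv_particles`.
#' @param ... unused.
#' @return tibble with subject_id, particle, x, y, z.
#' @export
tidy.rv_particles <- function(x, ...) {
  K <- dim(x$points)[1]; M <- x$M
  xs <- as.vector(t(x$points[, , 1]))
  ys <- as.vector(t(x$points[, , 2]))
  zs <- as.vector(t(x$points[, , 3]))
  tibble::tibble(subject_id = rep(x$subject_ids, each = M),
                 particle = rep(seq_len(M), K), x = xs, y = ys, z = zs)
}

# ---- .particles text IO ----------------------------------------------------

#' Read and write ShapeWorks-style `.particles` files
#'
#' One particle per line, three whitespace-separated coordinates (mm); tabs
#' and repeated spaces are accepted. `write_particles()` writes one file per
#' subject into `dir`; `read_particles()` reads a set of files back into a
#' particle system. Round trips are exact to 1e-6 mm.
#'
#' @param points M x 3 matrix (single subject) for [write_particle_file()].
#' @param path file path.
#' @param expected_m if given, error unless the file has exactly this many rows.
#' @return [read_particle_file()] returns an M x 3 matrix.
#' @export
read_particle_file <- function(path, expected_m = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed particle file '%s': line %d has %d columns (expected 3)",
                  path, bad[1], lengths(toks)[bad[1]]))
  }
  if (!is.null(expected_m) && length(toks) != expected_m) {
    abort(sprintf("particle file '%s' has %d lines, expected %d",
                  path, length(toks), expected_m))
  }
  m <- matrix(as.numeric(unlist(toks)), ncol = 3, byrow = TRUE)
  if (anyNA(m)) abort(sprintf("non-numeric coordinate in particle file '%s'", path))
  m
}

#' @rdname read_particle_file
#' @export
write_particle_file <- function(points, path) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  writeLines(sprintf("%.6f %.6f %.6f", points[, 1], points[, 2], points[, 3]), path)
  invisible(path)
}

#' @rdname read_particle_file
#' @param system an `rv_particles`.
#' @param dir directory for per-subject files `<subject_id>.particles`.
#' @export
write_particles <- function(system, dir) {
  stopifnot(inherits(system, "rv_particles"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(system$subject_ids)) {
    write_particle_file(system$points[k, , , drop = TRUE],
                        file.path(dir, paste0(system$subject_ids[k], ".particles")))
  }
  invisible(dir)
}

#' @rdname read_particle_file
#' @param paths particle files, one per subject (order defines subject order).
#' @export
read_particles <- function(paths, expected_m = NULL) {
  mats <- lapply(paths, read_particle_file, expected_m = expected_m)
  m <- unique(vapply(mats, nrow, integer(1)))
  if (length(m) != 1) abort("particle files disagree on particle count")
  pts <- array(0, dim = c(length(mats), m, 3))
  for (k in seq_along(mats)) pts[k, , ] <- mats[[k]]
  new_particle_system(pts, sub("\\.particles$", "", basename(paths)))
}

# ---- surface projection ----------------------------------------------------

#' Project points onto the zero level set of a distance transform
#'
#' Newton-style iteration `p <- p - D(p) * g / |g|^2` on the interpolated
#' signed distance `D` with central-difference gradient `g`, until
#' `|D| < tol`, at most `max_iter` sweeps.
#'
#' @param points N x 3 matrix (or length-3 vector) of world coordinates.
#' @param dt an `rv_dt`.
#' @param tol surface tolerance (mm); default half the voxel spacing.
#' @param max_iter maximum iterations (default 20).
#' @return matrix of projected points; errors with the worst residual if any
#'   point fails to converge.
#' @export
project_to_surface <- function(points, dt, tol = dt$spacing / 2, max_iter = 20L) {
  stopifnot(inherits(dt, "rv_dt"))
  p <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  active <- rep(TRUE, nrow(p))
  for (it in seq_len(max_iter)) {
    d <- interp3(dt$values, dt$spacing, dt$origin, p[active, , drop = FALSE])
    conv <- abs(d) < tol
    if (all(conv)) { active[active] <- FALSE } else {
      idx <- which(active)[!conv]
      g <- interp3_grad(dt$values, dt$spacing, dt$origin, p[idx, , drop = FALSE])
      # step of length |D| along the unit gradient: exact for a true signed
      # distance field, and bounded near the medial axis where |grad| < 1
      gn <- pmax(sqrt(rowSums(g^2)), 1e-6)
      p[idx, ] <- p[idx, , drop = FALSE] - (d[!conv] / gn) * g
      # keep iterates strictly inside the grid so the gradient stays defined
      lo <- dt$origin + dt$spacing
      hi <- dt$origin + (dim(dt$values) - 2) * dt$spacing
      for (ax in 1:3) p[idx, ax] <- pmin(pmax(p[idx, ax], lo[ax]), hi[ax])
      active[active] <- !conv
    }
    if (!any(active)) break
  }
  if (any(active)) {
    d <- interp3(dt$values, dt$spacing, dt$origin, p[active, , drop = FALSE])
    abort(sprintf("surface projection failed to converge for %d point(s); worst residual %.3f mm",
                  sum(active), max(abs(d))))
  }
  p
}

# ---- ground-truth bypass ---------------------------------------------------

#' Particle system from ground-truth correspondences
#'
#' Bypasses optimization: subsamples the cohort's shared parameter grid to M
#' points by greedy farthest-point selection on the undeformed template
#' (deterministically started at the apex pole sample), and uses the same
#' grid indices on every subject. Exact correspondence by construction.
#'
#' @param cohort an `rv_cohort`.
#' @param M number of particles (default 512).
#' @return an `rv_particles` with attribute `grid_index` (the selected
#'   parameter-grid indices, shared across subjects).
#' @export
attach_ground_truth <- function(cohort, M = 512) {
  stopifnot(inherits(cohort, "rv_cohort"))
  base_pts <- surface_points(cohort$base)
  if (M > nrow(base_pts)) {
    abort(sprintf("M = %d exceeds the %d available parameter-grid samples", M, nrow(base_pts)))
  }
  start <- which.max(cohort$base$theta)  # apex-most ring, phi = 0 (first column)
  sel <- farthest_point_indices(base_pts, M, start = start)
  K <- length(cohort$surfaces)
  pts <- array(0, dim = c(K, M, 3))
  for (k in seq_len(K)) {
    pts[k, , ] <- surface_points(cohort$surfaces[[k]])[sel, , drop = FALSE]
  }
  ps <- new_particle_system(pts, cohort$manifest$subject_id)
  attr(ps, "grid_index") <- sel
  ps
}
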