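# Segmentation masks, voxelization of synthetic surfaces, and cohort assembly.

#' Construct a segmentation mask object
#'
#' @param voxels 3D array (0/1 or logical); stored as integer.
#' @param spacing voxel spacing per axis (mm), length 1 or 3.
#' @param origin world coordinate (mm) of the center of voxel `[1,1,1]`.
#' @param subject_id identifier string.
#' @return an `rv_mask`.
#' @export
new_mask <- function(voxels, spacing, origin = c(0, 0, 0), subject_id = "subject") {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) abort("voxel spacing must be positive")
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  structure(list(voxels = v, spacing = spacing, origin = as.numeric(origin),
                 subject_id = subject_id),
            class = "rv_mask")
}

#' @export
print.rv_mask <- function(x, ...) {
  cat(sprintf("<rv_mask> %s: %s voxels at (%s) mm, %d foreground\n",
              x$subject_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = ", "), sum(x$voxels)))
  invisible(x)
}

mask_is_isotropic <- function(mask, tol = 1e-9) {
  diff(range(mask$spacing)) < tol
}

# foreground centroid in world mm
mask_centroid <- function(mask) {
  idx <- which(mask$voxels != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask has no foreground voxels")
  mask$origin + (colMeans(idx) - 1) * mask$spacing
}

#' Voxelize a star-shaped surface into a binary mask
#'
#' A voxel is foreground iff its center lies inside the surface (its distance
#' from the shape center is below the bilinearly interpolated radius in its
#' direction). The grid is centred on the shape's origin.
#'
#' @param surface an `rv_surface`.
#' @param spacing isotropic voxel spacing (mm).
#' @param dims grid dimensions (scalar or length 3); defaults to the smallest
#'   grid holding the shape with a 3-voxel margin.
#' @param subject_id identifier for the resulting mask.
#' @return an `rv_mask` whose origin places the shape center at the grid center.
#' @export
voxelize <- function(surface, spacing = 1.5, dims = NULL, subject_id = "subject") {
  stopifnot(inherits(surface, "rv_surface"))
  if (spacing <= 0) abort("spacing must be positive")
  rmax <- max(surface$r)
  if (rmax < spacing / 2) {
    abort("shape is smaller than half a voxel; refusing to produce an empty mask")
  }
  need <- ceiling(2 * rmax / spacing) + 6  # 3-voxel margin per side
  need <- need + (1 - need %% 2)           # odd: a voxel center at the shape center
  if (is.null(dims)) dims <- need
  dims <- rep(as.integer(dims), length.out = 3)
  if (any(dims < ceiling(2 * rmax / spacing) + 4)) {
    abort(sprintf("shape exceeds the grid (need at least %d voxels per axis for a 2-voxel margin)", need - 2))
  }
  # voxel centers, shape center at the grid center
  ax <- lapply(dims, function(n) (seq_len(n) - (n + 1) / 2) * spacing)
  rho2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  rho <- sqrt(rho2)
  z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dim = dims)
  y <- array(rep(rep(ax[[2]], each = dims[1]), dims[3]), dim = dims)
  x <- array(rep(ax[[1]], dims[2] * dims[3]), dim = dims)
  # voxel centers mapped back to the canonical (pose-free) frame
  pose <- surface$pose %||% diag(3)
  if (!isTRUE(all.equal(pose, diag(3)))) {
    q <- cbind(as.vector(x), as.vector(y), as.vector(z)) %*% pose
    x <- array(q[, 1], dim = dims); y <- array(q[, 2], dim = dims)
    z <- array(q[, 3], dim = dims)
  }
  theta <- acos(pmin(pmax(ifelse(rho > 0, z / rho, 1), -1), 1))
  phi <- atan2(y, x)
  rad <- array(surface_radius_at(surface, as.vector(theta), as.vector(phi)), dim = dims)
  vox <- rho < rad
  origin <- -(dims - 1) / 2 * spacing
  new_mask(vox, spacing, origin, subject_id)
}

#' Cohort specification for the synthetic study population
#'
#' Defaults mirror the study composition: 6 healthy volunteers, 27 comorbid
#' controls (4 pulmonary hypertension / 12 CHF / 11 other) and 21 TR patients
#' (3 / 9 / 9), with group deformations from [deformation_params()] over
#' smooth subject-level shape noise.
#'
#' @param group_sizes named counts for `healthy`, `control`, `tr`.
#' @param subgroup_fractions per-group named fractions over
#'   `phtn`/`chf`/`other`; must sum to 1.
#' @param deformation deformation amplitudes ([deformation_params()]).
#' @param noise_sd pointwise sd of subject shape noise (mm).
#' @param rot_sd_deg per-axis sd (degrees) of the per-subject rigid rotation
#'   jitter emulating residual alignment error (see
#'   [apply_group_deformation()]).
#' @param voxel_spacing isotropic spacing (mm) for voxelization.
#' @param grid_dims voxel grid dimensions (NULL = automatic).
#' @param resolution angular samples of the ground-truth parameter grid.
#' @param seed integer seed controlling all cohort randomness.
#' @return a validated `rv_cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(healthy = 6, control = 27, tr = 21),
                        subgroup_fractions = list(
                          control = c(phtn = 4 / 27, chf = 12 / 27, other = 11 / 27),
                          tr = c(phtn = 3 / 21, chf = 9 / 21, other = 9 / 21)),
                        deformation = deformation_params(),
                        noise_sd = 1.0,
                        rot_sd_deg = 2,
                        voxel_spacing = 1.5,
                        grid_dims = NULL,
                        resolution = 96,
                        seed = 1L) {
  if (any(group_sizes < 0)) abort("group counts must be >= 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (voxel_spacing <= 0) abort("voxel_spacing must be positive")
  for (g in names(subgroup_fractions)) {
    fr <- subgroup_fractions[[g]]
    if (abs(sum(fr) - 1) > 1e-8) {
      abort(sprintf("subgroup fractions for group '%s' must sum to 1", g))
    }
  }
  if (rot_sd_deg < 0) abort("rot_sd_deg must be >= 0")
  structure(list(group_sizes = group_sizes,
                 subgroup_fractions = subgroup_fractions,
                 deformation = deformation, noise_sd = noise_sd,
                 rot_sd_deg = rot_sd_deg,
                 voxel_spacing = voxel_spacing, grid_dims = grid_dims,
                 resolution = resolution, seed = as.integer(seed)),
            class = "rv_cohort_spec")
}

# deterministic largest-remainder allocation of n members to fractions
allocate_counts <- function(n, fractions) {
  if (n == 0) return(setNames(integer(length(fractions)), names(fractions)))
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(fractions))
}

#' Generate a synthetic cohort of RV-like shapes
#'
#' Deterministic given the spec's seed. Each subject is the template deformed
#' by its group/subgroup pattern plus an independent smooth noise field, with
#' exact ground-truth correspondence at the shared parameter grid, optionally
#' voxelized into a binary segmentation mask.
#'
#' @param spec an [cohort_spec()].
#' @param voxelize_masks if `FALSE`, skip voxelization (surfaces and
#'   ground-truth correspondence only); useful when downstream analysis runs
#'   on ground-truth correspondences.
#' @return an `rv_cohort`: list with `surfaces` (list of `rv_surface`),
#'   `masks` (list of `rv_mask` or NULL), and a `manifest` tibble
#'   (subject_id, group, subgroup, seed).
#' @export
generate_cohort <- function(spec = cohort_spec(), voxelize_masks = TRUE) {
  stopifnot(inherits(spec, "rv_cohort_spec"))
  base <- generate_base_surface(spec$resolution)
  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  subgroups <- unlist(lapply(names(spec$group_sizes), function(g) {
    n <- spec$group_sizes[[g]]
    fr <- spec$subgroup_fractions[[g]]
    if (is.null(fr) || n == 0) return(rep("none", n))
    rep(names(fr), times = allocate_counts(n, fr))
  }), use.names = FALSE)
  n <- length(groups)
  ids <- sprintf("s%03d_%s", seq_len(n), groups)
  set.seed(spec$seed)
  surfaces <- vector("list", n)
  masks <- if (voxelize_masks) vector("list", n) else NULL
  for (i in seq_len(n)) {
    s <- apply_group_deformation(base, groups[i], subgroups[i],
                                 params = spec$deformation,
                                 noise_sd = spec$noise_sd,
                                 rot_sd_deg = spec$rot_sd_deg)
    surfaces[[i]] <- s
    if (voxelize_masks) {
      masks[[i]] <- voxelize(s, spacing = spec$voxel_spacing,
                             dims = spec$grid_dims, subject_id = ids[i])
    }
  }
  manifest <- tibble::tibble(subject_id = ids, group = groups,
                             subgroup = subgroups, seed = spec$seed)
  structure(list(surfaces = surfaces, masks = masks, manifest = manifest,
                 spec = spec, base = base),
            class = "rv_cohort")
}

#' @export
print.rv_cohort <- function(x, ...) {
  cat(sprintf("<rv_cohort> %d subjects (%s)%s\n", nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$group)),
                            table(x$manifest$group)), collapse = ", "),
              if (is.null(x$masks)) ", surfaces only" else ", voxelized"))
  invisible(x)
}

#' Write cohort masks, correspondences and manifest to disk
#'
#' Masks go to NIfTI (`.nii.gz`) or MetaImage (`.mhd`/`.raw`), ground-truth
#' correspondences to ShapeWorks-style `.particles` text files (one `x y z`
#' per line), and the manifest to CSV.
#'
#' @param cohort an `rv_cohort` with masks.
#' @param dir output directory (created if missing).
#' @param format `"nifti"` or `"metaimage"`.
#' @return the manifest tibble with a `file` column, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "metaimage")) {
  format <- match.arg(format)
  if (is.null(cohort$masks)) abort("cohort has no masks; regenerate with voxelize_masks = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "nifti") ".nii.gz" else ".mhd"
  files <- character(nrow(cohort$manifest))
  for (i in seq_along(cohort$masks)) {
    f <- file.path(dir, paste0(cohort$manifest$subject_id[i], ext))
    write_mask(cohort$masks[[i]], f)
    files[i] <- f
    pts <- surface_points(cohort$surfaces[[i]])
    write_particle_file(pts, file.path(dir, paste0(cohort$manifest$subject_id[i], ".particles")))
  }
  manifest <- dplyr::mutate(cohort$manifest, file = files)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# ---- volume IO -------------------------------------------------------------

#' Read / write segmentation volumes
#'
#' NIfTI via the RNifti package; MetaImage (`.mhd` + `.raw`) via a minimal
#' reader/writer (MET_UCHAR/MET_SHORT/MET_FLOAT, uncompressed).
#'
#' @param mask an `rv_mask` (or `rv_dt` for distance transforms, written as
#'   32-bit float).
#' @param path file path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @return `read_mask()` returns an `rv_mask`.
#' @export
write_mask <- function(mask, path) {
  x <- if (inherits(mask, "rv_dt")) mask$values else mask$voxels
  if (grepl("\\.nii(\\.gz)?$", path)) {
    sp <- if (inherits(mask, "rv_dt")) rep(mask$spacing, 3) else mask$spacing
    attr(x, "pixdim") <- sp
    img <- RNifti::asNifti(x, datatype = if (inherits(mask, "rv_dt")) "float" else "uint8")
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mhd$", path)) {
    raw_path <- sub("\\.mhd$", ".raw", path)
    type <- if (inherits(mask, "rv_dt")) "MET_FLOAT" else "MET_UCHAR"
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             sprintf("ElementSpacing = %g %g %g", mask$spacing[1], mask$spacing[2], mask$spacing[3]),
             sprintf("Offset = %g %g %g", mask$origin[1], mask$origin[2], mask$origin[3]),
             sprintf("DimSize = %d %d %d", dim(x)[1], dim(x)[2], dim(x)[3]),
             sprintf("ElementType = %s", type),
             sprintf("ElementDataFile = %s", basename(raw_path)))
    writeLines(hdr, path)
    con <- file(raw_path, "wb")
    on.exit(close(con))
    if (type == "MET_FLOAT") {
      writeBin(as.numeric(x), con, size = 4, endian = "little")
    } else {
      writeBin(as.raw(as.integer(x)), con)
    }
  } else {
    abort("unsupported volume format; use .nii, .nii.gz or .mhd")
  }
  invisible(path)
}

#' @rdname write_mask
#' @param subject_id identifier attached to the mask read.
#' @export
read_mask <- function(path, subject_id = sub("\\.(nii(\\.gz)?|mhd)$", "", basename(path))) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- attr(img, "pixdim")
    if (is.null(sp)) sp <- RNifti::pixdim(img)
    new_mask(array(as.integer(img != 0), dim = dim(img)), sp[1:3],
             subject_id = subject_id)
  } else if (grepl("\\.mhd$", path)) {
    hdr <- readLines(path)
    get <- function(key) {
      ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
      trimws(sub("^[^=]*=", "", ln))
    }
    dims <- as.integer(strsplit(get("DimSize"), " +")[[1]])
    sp <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
    off <- get("Offset")
    origin <- if (is.na(off)) c(0, 0, 0) else as.numeric(strsplit(off, " +")[[1]])
    type <- get("ElementType")
    raw_path <- file.path(dirname(path), get("ElementDataFile"))
    con <- file(raw_path, "rb")
    on.exit(close(con))
    n <- prod(dims)
    vals <- switch(type,
      MET_UCHAR = as.integer(readBin(con, "raw", n)),
      MET_SHORT = readBin(con, "integer", n, size = 2, endian = "little"),
      MET_FLOAT = readBin(con, "numeric", n, size = 4, endian = "little"),
      abort(sprintf("unsupported MetaImage ElementType '%s'", type)))
    new_mask(array(as.integer(vals != 0), dim = dims), sp, origin, subject_id)
  } else {
    abort("unsupported volume format; use .nii, .nii.gz or .mhd")
  }
}
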