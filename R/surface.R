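# Synthetic star-shaped RV-like surfaces.
#
# The template is a radial surface r(theta, phi) about the origin: theta is the
# polar angle measured from the basal (tricuspid) pole at +z down to the apex
# at -z, phi the azimuth with the free wall centred at phi = 0 and the septum
# at phi = pi. Star-shapedness (r > 0 everywhere) makes voxelization and exact
# ground-truth correspondence trivial: the shared (theta, phi) grid IS the
# correspondence.

TEMPLATE_AX <- 24   # equatorial semi-axis, mm
TEMPLATE_AZ <- 38   # polar semi-axis, mm
SH_NOISE_LMAX <- 6  # max spherical-harmonic degree of the subject noise field

# Gaussian bump centres/widths in template parameter coordinates. Peaks are 1
# so a deformation's amplitude is exactly its maximum radial displacement.
BUMP_DEFS <- list(
  bulge    = list(theta_c = 0.55 * pi, s_theta = 0.10 * pi, phi_c = 0,  s_phi = pi / 5),
  apex     = list(theta_c = 0.82 * pi, s_theta = 0.07 * pi, phi_c = NA, s_phi = NA),
  base     = list(theta_c = 0.13 * pi, s_theta = 0.07 * pi, phi_c = NA, s_phi = NA),
  pinch    = list(theta_c = 0.55 * pi, s_theta = 0.09 * pi, phi_c = 0,  s_phi = pi / 4.5),
  narrow   = list(theta_c = 0.55 * pi, s_theta = 0.10 * pi, phi_c = NA, s_phi = NA)
)

bump_field <- function(theta, phi, def) {
  tpart <- exp(-(theta - def$theta_c)^2 / (2 * def$s_theta^2))
  if (is.na(def$phi_c)) {
    outer(tpart, rep(1, length(phi)))
  } else {
    dphi <- wrap_angle(phi - def$phi_c)
    outer(tpart, exp(-dphi^2 / (2 * def$s_phi^2)))
  }
}

#' Default group deformation amplitudes (mm)
#'
#' Amplitudes of the smooth radial deformation fields applied on top of the
#' shared template: `bulge_amp` (outward free-wall protrusion in the TR group),
#' `apex_blunt_amp` (blunting of the apical region in TR), `base_width_amp`
#' (widening of the basal cap in TR), and `midwall_pinch_amp` (inward
#' mid-free-wall displacement in comorbid controls; the same amplitude drives
#' the circumferential mid-cavity narrowing of the pulmonary-hypertension
#' control subgroup).
#'
#' @param bulge_amp,apex_blunt_amp,base_width_amp,midwall_pinch_amp amplitudes
#'   in mm; each equals the peak radial displacement of its field.
#' @return named list of amplitudes.
#' @export
deformation_params <- function(bulge_amp = 5, apex_blunt_amp = 3,
                               base_width_amp = 4, midwall_pinch_amp = 2.5) {
  p <- list(bulge_amp = bulge_amp, apex_blunt_amp = apex_blunt_amp,
            base_width_amp = base_width_amp, midwall_pinch_amp = midwall_pinch_amp)
  if (!all(vapply(p, is.finite, logical(1)))) abort("deformation amplitudes must be finite")
  p
}

#' Generate the canonical RV-like template surface
#'
#' A smooth star-shaped closed surface: a prolate ellipsoidal profile with a
#' crescent-like (septally flattened) cross-section and a mild azimuthal bend,
#' so the shape has no mirror symmetry and rigid alignment is well-posed.
#' Designated regions (free-wall patch, apical pole, basal cap) are fixed in
#' template parameter coordinates; see [surface_patches()].
#'
#' @param resolution samples per angular axis (minimum 16). The surface is
#'   sampled at cell-centred polar angles `theta_i = (i - 1/2) * pi / n` and
#'   azimuths `phi_j = (j - 1) * 2 * pi / n`.
#' @return an `rv_surface`: list with `theta`, `phi`, radial matrix `r`
#'   (mm, `resolution x resolution`), and group labels.
#' @export
generate_base_surface <- function(resolution = 96) {
  if (resolution < 16) {
    abort(sprintf("resolution must be at least 16 samples per angular axis (got %d)", resolution))
  }
  n <- as.integer(resolution)
  theta <- (seq_len(n) - 0.5) * pi / n
  phi <- (seq_len(n) - 1) * 2 * pi / n
  ax <- TEMPLATE_AX; az <- TEMPLATE_AZ
  ellip <- ax * az / sqrt((az * sin(theta))^2 + (ax * cos(theta))^2)
  septal <- 1 - 0.22 * outer(sin(theta), (1 - cos(phi)) / 2)
  bend <- 1 + 0.10 * outer(sin(2 * theta), sin(phi))
  r <- outer(ellip, rep(1, n)) * septal * bend
  structure(list(theta = theta, phi = phi, r = r, pose = diag(3),
                 group = "template", subgroup = "none"),
            class = "rv_surface")
}

#' @export
print.rv_surface <- function(x, ...) {
  cat(sprintf("<rv_surface> %dx%d radial grid, r in [%.1f, %.1f] mm, group=%s/%s\n",
              length(x$theta), length(x$phi), min(x$r), max(x$r), x$group, x$subgroup))
  invisible(x)
}

#' Template patch masks in parameter coordinates
#'
#' Fixed, documented parameter-space regions used for deformation placement
#' and localization tests: `free_wall` (mid-ventricular band around phi = 0),
#' `apex` (polar cap at theta > 0.85 pi), `base` (basal cap at
#' theta < 0.18 pi) and `mid` (circumferential mid-cavity band).
#'
#' @param surface an `rv_surface`.
#' @return named list of logical matrices on the surface's (theta, phi) grid.
#' @export
surface_patches <- function(surface) {
  th <- surface$theta; ph <- wrap_angle(surface$phi)
  ones_t <- rep(TRUE, length(th)); ones_p <- rep(TRUE, length(ph))
  list(
    free_wall = outer(th > 0.35 * pi & th < 0.80 * pi, abs(ph) < pi / 3, "&"),
    apex      = outer(th > 0.85 * pi, ones_p, "&"),
    base      = outer(th < 0.18 * pi, ones_p, "&"),
    mid       = outer(th > 0.40 * pi & th < 0.70 * pi, ones_p, "&")
  )
}

# --- smooth subject-level noise: random spherical-harmonic field ------------

# real orthonormal spherical harmonics up to degree lmax, evaluated on the
# (theta, phi) grid; returns (ntheta*nphi) x nbasis matrix, column-major in
# theta. Degree 0 is excluded (pure size jitter is not shape noise here).
sh_cache <- new.env(parent = emptyenv())

sh_basis_grid <- function(theta, phi, lmax = SH_NOISE_LMAX) {
  key <- paste(length(theta), length(phi), lmax, signif(theta[1], 12), sep = "_")
  if (!is.null(sh_cache[[key]])) return(sh_cache[[key]])
  x <- cos(theta)
  nt <- length(theta); np <- length(phi)
  cols <- list()
  for (l in seq_len(lmax)) {
    P <- pracma::legendre(l, x)  # (l+1) x nt, rows m = 0..l
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      plm <- nrm * P[m + 1, ]
      if (m == 0) {
        cols[[length(cols) + 1]] <- outer(plm, rep(1, np))
      } else {
        cols[[length(cols) + 1]] <- sqrt(2) * outer(plm, cos(m * phi))
        cols[[length(cols) + 1]] <- sqrt(2) * outer(plm, sin(m * phi))
      }
    }
  }
  B <- vapply(cols, as.vector, numeric(nt * np))
  sh_cache[[key]] <- B
  B
}

# pointwise variance of the unit-coefficient field is sum_l (2l+1)/(4pi)
sh_field_sd <- function(lmax = SH_NOISE_LMAX) {
  sqrt(sum(2 * seq_len(lmax) + 1) / (4 * pi))
}

#' Apply group-level deformation and subject noise to the template
#'
#' TR shapes receive an outward free-wall bulge, apical blunting and basal
#' widening; comorbid controls an inward mid-free-wall displacement; the
#' pulmonary-hypertension control subgroup an additional circumferential
#' mid-cavity narrowing ("streamlining"). Subject-level variation is a smooth
#' random radial field (iid normal spherical-harmonic coefficients, degrees
#' 1..6) scaled so its pointwise standard deviation is `noise_sd` everywhere;
#' it is added last. Draws come from the current R random-number stream, so
#' seed with [set.seed()] for reproducibility.
#'
#' @param base template from [generate_base_surface()].
#' @param group one of `"healthy"`, `"control"`, `"tr"`.
#' @param subgroup one of `"none"`, `"phtn"`, `"chf"`, `"other"`.
#' @param params amplitudes from [deformation_params()].
#' @param noise_sd pointwise sd of the radial noise field (mm, >= 0).
#' @param rot_sd_deg per-axis sd (degrees) of a small random rigid rotation
#'   applied to the whole subject, emulating the residual misalignment that
#'   survives translation-only rigid alignment of real segmentations; 0
#'   disables it. The radial map stays in the canonical frame and the
#'   rotation is stored as the surface's `pose`.
#' @return a deformed `rv_surface`; errors if any radius is driven to <= 0.
#' @export
apply_group_deformation <- function(base, group, subgroup = "none",
                                    params = deformation_params(),
                                    noise_sd = 0, rot_sd_deg = 0) {
  stopifnot(inherits(base, "rv_surface"))
  group <- match.arg(group, c("healthy", "control", "tr", "template"))
  subgroup <- match.arg(subgroup, c("none", "phtn", "chf", "other"))
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  th <- base$theta; ph <- base$phi
  delta <- matrix(0, length(th), length(ph))
  if (group == "tr") {
    delta <- delta +
      params$bulge_amp * bump_field(th, ph, BUMP_DEFS$bulge) +
      params$apex_blunt_amp * bump_field(th, ph, BUMP_DEFS$apex) +
      params$base_width_amp * bump_field(th, ph, BUMP_DEFS$base)
  }
  if (group == "control") {
    delta <- delta - params$midwall_pinch_amp * bump_field(th, ph, BUMP_DEFS$pinch)
    if (subgroup == "phtn") {
      delta <- delta - params$midwall_pinch_amp * bump_field(th, ph, BUMP_DEFS$narrow)
    }
  }
  if (noise_sd > 0) {
    B <- sh_basis_grid(th, ph)
    coefs <- rnorm(ncol(B), sd = noise_sd / sh_field_sd())
    delta <- delta + matrix(B %*% coefs, length(th), length(ph))
  }
  r <- base$r + delta
  if (any(r <= 0)) {
    abort("deformation drives the radius non-positive; amplitude too large for the template")
  }
  pose <- base$pose %||% diag(3)
  if (rot_sd_deg > 0) {
    pose <- rotation_matrix(rnorm(3, sd = rot_sd_deg * pi / 180)) %*% pose
  }
  structure(list(theta = th, phi = ph, r = r, pose = pose,
                 group = group, subgroup = subgroup),
            class = "rv_surface")
}

# rotation matrix from a rotation vector (axis * angle), Rodrigues formula
rotation_matrix <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-12) return(diag(3))
  k <- omega / th
  Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
}

#' Ground-truth correspondence points of a surface
#'
#' Samples the surface at its canonical parameter grid: point (i, j) is
#' `r(theta_i, phi_j)` times the unit direction, hence lies exactly on the
#' surface and occupies the same parameter location on every subject.
#'
#' @param surface an `rv_surface`.
#' @return `(ntheta * nphi) x 3` matrix of points (mm), theta varying fastest,
#'   in the subject frame (the surface's rigid `pose` applied).
#' @export
surface_points <- function(surface) {
  th <- surface$theta; ph <- surface$phi
  st <- sin(th); ct <- cos(th)
  r <- surface$r
  x <- r * outer(st, cos(ph))
  y <- r * outer(st, sin(ph))
  z <- r * outer(ct, rep(1, length(ph)))
  pts <- cbind(as.vector(x), as.vector(y), as.vector(z))
  pose <- surface$pose %||% diag(3)
  pts %*% t(pose)
}

#' Enclosed volume of a star-shaped surface
#'
#' Analytic (divergence-theorem) volume of the region bounded by the radial
#' surface: `V = (1/3) * int r^3 sin(theta) dtheta dphi`, evaluated by the
#' midpoint rule on the parameter grid.
#'
#' @param surface an `rv_surface`.
#' @return volume in mm^3.
#' @export
surface_volume <- function(surface) {
  dth <- pi / length(surface$theta)
  dph <- 2 * pi / length(surface$phi)
  sum(surface$r^3 * sin(surface$theta)) * dth * dph / 3
}

# bilinear interpolation of the radial map at arbitrary (theta, phi);
# periodic in phi, clamped in theta (nearest ring at the poles)
surface_radius_at <- function(surface, theta, phi) {
  nt <- length(surface$theta); np <- length(surface$phi)
  ut <- theta / (pi / nt) + 0.5        # continuous row index
  ut <- pmin(pmax(ut, 1), nt)
  i0 <- pmin(floor(ut), nt - 1); ft <- ut - i0
  up <- (phi %% (2 * pi)) / (2 * pi / np) + 1   # continuous col index
  j0 <- floor(up); fp <- up - j0
  j0 <- ((j0 - 1) %% np) + 1
  j1 <- (j0 %% np) + 1
  r <- surface$r
  r00 <- r[cbind(i0, j0)]; r10 <- r[cbind(i0 + 1, j0)]
  r01 <- r[cbind(i0, j1)]; r11 <- r[cbind(i0 + 1, j1)]
  (r00 * (1 - ft) + r10 * ft) * (1 - fp) + (r01 * (1 - ft) + r11 * ft) * fp
}
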