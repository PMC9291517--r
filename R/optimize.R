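# Particle-based correspondence optimization.
#
# Particles are constrained to each subject's zero level set and evolve by
# gradient descent on
#   alpha * (ensemble term)  +  (1 - alpha) * (sampling term)
# where the sampling term is, per shape, the negative Gaussian-kernel
# repulsion entropy sum_i -log sum_{j != i} exp(-|p_i - p_j|^2 / (2 sigma^2))
# (minimized by uniform coverage), and the ensemble term is the regularized
# log-determinant of the cross-subject covariance of the flattened particle
# vectors (minimized by compact correspondence). Particles are grown by a
# 1 -> 2 -> ... -> M splitting schedule; split offsets are drawn once per
# split from the seeded generator and shared across subjects, so identical
# shapes receive identical landmarks.

#' Optimizer configuration
#'
#' @param M target particle count (default 512, a power of two).
#' @param iterations_per_split gradient iterations per schedule stage; the
#'   final stage runs one extra phase of this length.
#' @param step_size maximum particle displacement per accepted step (mm);
#'   backtracking halves it on objective increase.
#' @param sigma_factor kernel bandwidth scale: at m particles the Gaussian
#'   bandwidth is `sigma_factor * R_eff * sqrt(4*pi/m)`, with `R_eff` the
#'   cohort's equivalent-sphere radius; `R_eff * sqrt(4*pi/m)` is about one
#'   inter-particle spacing, and the default 0.5 keeps the kernel local
#'   enough that nearest-neighbor repulsion dominates (preventing newly
#'   split particle pairs from re-merging).
#' @param alpha relative weight of the ensemble (correspondence) term in
#'   `[0, 1]`, applied after separate normalization of the two gradient
#'   families; ramped linearly from 0 over the first stage. The default 0.8
#'   keeps cross-subject correspondence locked against the slow drift that
#'   the per-shape repulsion dynamics otherwise induce on similar (but not
#'   identical) surfaces.
#' @param epsilon covariance ridge (mm^2) regularizing the ensemble term.
#' @param seed integer seed for split offsets.
#' @param tol_surf surface tolerance (mm); default half the voxel spacing.
#' @return an `rv_opt_config`.
#' @export
optimizer_config <- function(M = 512, iterations_per_split = 40, step_size = 1.0,
                             sigma_factor = 0.5, alpha = 0.8, epsilon = 1e-2,
                             seed = 17L, tol_surf = NULL) {
  if (M < 1) abort("M must be >= 1")
  if (step_size <= 0) abort("step_size must be positive")
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  structure(list(M = as.integer(M), iterations_per_split = as.integer(iterations_per_split),
                 step_size = step_size, sigma_factor = sigma_factor,
                 alpha = alpha, epsilon = epsilon, seed = as.integer(seed),
                 tol_surf = tol_surf),
            class = "rv_opt_config")
}

# sampling (repulsion) cost and gradient for one shape; P is m x 3. The cost
# is the negative particle entropy ~ sum_i log( sum_{j!=i} w_ij ) with
# per-particle bandwidths: minimizing it spreads particles uniformly (each
# particle descends its own kernel density estimate). Bandwidths adapt to the
# current nearest-neighbor distance (clamped to [floor, sigma]) and are held
# frozen within an iteration, so newly split near-coincident pairs feel a
# repulsion comparable to the global gradient scale and always separate.
particle_bandwidths <- function(P, sigma, floor_s) {
  m <- nrow(P)
  if (m < 2) return(rep(sigma, m))
  D2 <- as.matrix(stats::dist(P))^2
  diag(D2) <- Inf
  nn <- sqrt(apply(D2, 1, min))
  pmin(pmax(nn, floor_s), sigma)
}

sampling_cost <- function(P, si) {
  m <- nrow(P)
  if (m < 2) return(0)
  D2 <- as.matrix(stats::dist(P))^2
  W <- exp(-D2 / (2 * si^2)); diag(W) <- 0  # row i uses bandwidth si[i]
  sum(log(pmax(rowSums(W), 1e-300)))
}

sampling_grad <- function(P, si) {
  m <- nrow(P)
  if (m < 2) return(matrix(0, m, 3))
  D2 <- as.matrix(stats::dist(P))^2
  W <- exp(-D2 / (2 * si^2)); diag(W) <- 0
  Z <- pmax(rowSums(W), 1e-300)
  A <- (W / Z) / si^2      # as i: own-row bandwidth
  B <- t((W / Z) / si^2)   # as j in others' denominators: their bandwidth
  Mw <- A + B
  -(rowSums(Mw) * P - Mw %*% P)
}

# ensemble cost and per-subject gradient from the K x 3m coordinate matrix
ensemble_cost <- function(Y, epsilon) {
  K <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  G <- tcrossprod(Yc) / (K - 1)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  sum(log(pmax(ev, 0) + epsilon))
}

ensemble_grad <- function(Y, epsilon) {
  K <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  G <- tcrossprod(Yc) / (K - 1)
  Gr <- solve(G + diag(epsilon, K), Yc) * (2 / (K - 1))
  sweep(Gr, 2, colMeans(Gr))  # chain rule through column centering
}

points_to_Y <- function(P_list) {
  t(vapply(P_list, function(P) as.vector(t(P)), numeric(nrow(P_list[[1]]) * 3)))
}

check_in_grid <- function(P_list, dt, subject_ids) {
  dims <- dim(dt$values)
  lo <- dt$origin; hi <- dt$origin + (dims - 1) * dt$spacing
  for (k in seq_along(P_list)) {
    P <- P_list[[k]]
    bad <- which(P[, 1] < lo[1] | P[, 1] > hi[1] | P[, 2] < lo[2] | P[, 2] > hi[2] |
                   P[, 3] < lo[3] | P[, 3] > hi[3])
    if (length(bad) > 0) {
      abort(sprintf("particle %d of subject %s escaped the grid", bad[1], subject_ids[k]))
    }
  }
}

#' Optimize correspondence particles across a cohort of distance transforms
#'
#' Gradient-descent particle optimization with a particle-splitting schedule
#' (see the package overview for the objective). Deterministic given the
#' config seed; the objective is non-increasing (backtracking rejects
#' increasing steps, stalling instead).
#'
#' @param dts list of `rv_dt` on identical grids (2 or more subjects).
#' @param config an [optimizer_config()].
#' @param subject_ids optional subject identifiers.
#' @param verbose print per-stage progress.
#' @return an `rv_particles` with attributes `objective` (per-iteration
#'   trace, final stage) and `config`.
#' @export
optimize_particles <- function(dts, config = optimizer_config(), subject_ids = NULL,
                               verbose = FALSE) {
  K <- length(dts)
  if (K < 2) abort("correspondence optimization needs at least 2 subjects")
  ref <- dts[[1]]
  for (d in dts) {
    # identical dims and spacing required; origins may differ by the
    # sub-voxel remainder that exact centroid alignment leaves behind
    if (!identical(dim(d$values), dim(ref$values)) ||
        abs(d$spacing - ref$spacing) > 1e-9 ||
        max(abs(d$origin - ref$origin)) > ref$spacing) {
      abort("all distance transforms must share one grid; run align_rigid first")
    }
  }
  if (is.null(subject_ids)) {
    subject_ids <- vapply(seq_len(K), function(k) dts[[k]]$subject_id %||% sprintf("s%03d", k),
                          character(1))
  }
  spacing <- ref$spacing
  tol <- config$tol_surf %||% (spacing / 2)
  # equivalent-sphere radius from mean enclosed volume
  vols <- vapply(dts, function(d) sum(d$values < 0) * spacing^3, numeric(1))
  r_eff <- (3 * mean(vols) / (4 * pi))^(1 / 3)
  sigma_for <- function(m) max(config$sigma_factor * r_eff * sqrt(4 * pi / m), spacing / 2)

  set.seed(config$seed)
  # initial particle: a common start OUTSIDE the shapes on the +x axis, where
  # the distance-field gradient is well-conditioned, so projection lands at a
  # consistent anatomical location on every subject (a start at the shape
  # center would project along the noisy medial-axis gradient)
  dims <- dim(ref$values)
  center <- ref$origin + (dims - 1) / 2 * spacing
  start <- center + c((dims[1] - 3) / 2 * spacing, 0, 0)
  P <- lapply(dts, function(d) project_to_surface(start, d, tol = tol))

  total_obj <- function(P_list, si_list, alpha) {
    samp <- sum(vapply(seq_along(P_list),
                       function(k) sampling_cost(P_list[[k]], si_list[[k]]),
                       numeric(1)))
    ens <- if (alpha > 0) ensemble_cost(points_to_Y(P_list), config$epsilon) else 0
    alpha * ens + (1 - alpha) * samp
  }

  n_stage <- ceiling(log2(config$M)) + 1
  stage_m <- pmin(2^(seq_len(n_stage) - 1), config$M)
  trace <- numeric(0)
  first_stage <- TRUE
  for (si in seq_along(stage_m)) {
    m <- stage_m[si]
    if (m > nrow(P[[1]])) {
      # split: duplicate with a shared random offset per particle, applied in
      # each subject's tangent plane (a normal offset would vanish under
      # surface projection), then project
      off <- matrix(rnorm(nrow(P[[1]]) * 3), ncol = 3)
      off <- off / sqrt(rowSums(off^2))
      P <- lapply(seq_len(K), function(k) {
        nrm <- interp3_grad(dts[[k]]$values, spacing, dts[[k]]$origin, P[[k]])
        nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-9)
        toff <- off - rowSums(off * nrm) * nrm
        toff <- toff / pmax(sqrt(rowSums(toff^2)), 1e-6) * (0.5 * spacing)
        newP <- rbind(P[[k]], P[[k]] + toff)
        project_to_surface(newP, dts[[k]], tol = tol)[seq_len(m), , drop = FALSE]
      })
    }
    sigma <- sigma_for(m)
    final_stage <- si == length(stage_m)
    n_it <- config$iterations_per_split * (1L + as.integer(final_stage))
    step <- config$step_size
    obj <- NA_real_
    for (it in seq_len(n_it)) {
      alpha_t <- if (first_stage) config$alpha * (it / n_it) else config$alpha
      si_list <- lapply(P, particle_bandwidths, sigma = sigma, floor_s = spacing / 2)
      obj <- total_obj(P, si_list, alpha_t)
      Yg <- if (alpha_t > 0) ensemble_grad(points_to_Y(P), config$epsilon) else NULL
      # normalize the two gradient families separately before mixing: the
      # log-det correspondence gradient saturates (~1/deviation) once shapes
      # de-correspond, so a joint normalization would let the sampling term
      # drown it; separate scaling keeps its alpha-share of every step
      Gs <- lapply(seq_len(K), function(k) sampling_grad(P[[k]], si_list[[k]]))
      gs_max <- max(vapply(Gs, function(g) max(sqrt(rowSums(g^2))), numeric(1)), 1e-12)
      if (!is.null(Yg)) {
        Ge <- lapply(seq_len(K), function(k) matrix(Yg[k, ], ncol = 3, byrow = TRUE))
        ge_max <- max(vapply(Ge, function(g) max(sqrt(rowSums(g^2))), numeric(1)), 1e-12)
      }
      G <- vector("list", K)
      gmax <- 0
      for (k in seq_len(K)) {
        g <- (1 - alpha_t) * Gs[[k]] / gs_max
        if (!is.null(Yg)) g <- g + alpha_t * Ge[[k]] / ge_max
        # tangent projection: remove the surface-normal component
        nrm <- interp3_grad(dts[[k]]$values, spacing, dts[[k]]$origin, P[[k]])
        nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-9)
        g <- g - rowSums(g * nrm) * nrm
        G[[k]] <- g
        gmax <- max(gmax, sqrt(rowSums(g^2)))
      }
      if (gmax < 1e-12) break
      s <- step
      accepted <- FALSE
      for (bt in 1:8) {
        cand <- lapply(seq_len(K), function(k) {
          project_to_surface(P[[k]] - (s / gmax) * G[[k]], dts[[k]], tol = tol)
        })
        cobj <- total_obj(cand, si_list, alpha_t)  # bandwidths frozen in-iteration
        if (cobj <= obj + 1e-9 * (1 + abs(obj))) {
          P <- cand; obj <- cobj; accepted <- TRUE
          break
        }
        s <- s / 2
      }
      if (final_stage && it > config$iterations_per_split) trace <- c(trace, obj)
      if (!accepted) next  # stall: keep positions, objective unchanged
    }
    first_stage <- FALSE
    check_in_grid(P, ref, subject_ids)
    if (verbose) {
      Y <- points_to_Y(P)
      tv <- mean(colSums(sweep(Y, 2, colMeans(Y))^2) / max(K - 1, 1))
      message(sprintf("stage m=%4d  sigma=%5.2f  obj=%10.3f  mean coord var=%8.4f",
                      m, sigma, obj, tv))
    }
  }
  pts <- array(0, dim = c(K, config$M, 3))
  for (k in seq_len(K)) pts[k, , ] <- P[[k]]
  ps <- new_particle_system(pts, subject_ids)
  attr(ps, "objective") <- trace
  attr(ps, "config") <- config
  ps
}
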