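# PCA shape space over flattened correspondence coordinates.

#' Build a shape matrix from a particle system
#'
#' Flattens each subject's particles to a row `(x1, y1, z1, ..., xM, yM, zM)`
#' and attaches group labels.
#'
#' @param particles an `rv_particles`.
#' @param labels tibble/data.frame with columns `subject_id`, `group` and
#'   optionally `subgroup` (e.g. a cohort manifest); matched by subject id.
#' @return an `rv_shape_matrix`: K x 3M numeric matrix with a `labels`
#'   attribute (tibble aligned to the rows).
#' @export
shape_matrix <- function(particles, labels = NULL) {
  stopifnot(inherits(particles, "rv_particles"))
  K <- dim(particles$points)[1]
  X <- t(vapply(seq_len(K), function(k) as.vector(t(particles$points[k, , ])),
                numeric(particles$M * 3)))
  rownames(X) <- particles$subject_ids
  if (is.null(labels)) {
    labels <- tibble::tibble(subject_id = particles$subject_ids,
                             group = NA_character_, subgroup = NA_character_)
  } else {
    labels <- tibble::as_tibble(labels)
    ord <- match(particles$subject_ids, labels$subject_id)
    if (anyNA(ord)) abort("labels are missing some subject ids")
    labels <- labels[ord, ]
    if (!"subgroup" %in% names(labels)) labels$subgroup <- "none"
  }
  structure(X, labels = labels, class = c("rv_shape_matrix", "matrix", "array"))
}

shape_labels <- function(x) attr(x, "labels")

#' Fit a PCA shape model
#'
#' Centered PCA by singular-value decomposition of the K x 3M matrix (thin
#' decomposition; at most `min(K - 1, 3M)` modes). Eigenvalues are sample
#' variances (normalized by K - 1). Each mode's sign is fixed so its
#' largest-magnitude component is positive, making loadings reproducible.
#'
#' @param x an `rv_shape_matrix` (or plain matrix) with K >= 2 rows.
#' @return an `rv_pca`: list with `mean` (3M), `modes` (3M x m, orthonormal
#'   columns), `eigenvalues` (descending, mm^2), `loadings` (K x m
#'   projections of centered rows), `subject_ids`, `labels`.
#' @export
fit_pca <- function(x) {
  K <- nrow(x)
  if (is.null(K) || K < 2) abort("PCA needs at least 2 shapes")
  mu <- colMeans(x)
  Yc <- sweep(unclass(x), 2, mu)
  n_modes <- min(K - 1, ncol(x))
  sv <- svd(Yc, nu = n_modes, nv = n_modes)
  modes <- sv$v
  # deterministic sign: largest-|component| of each mode positive
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  loadings <- Yc %*% modes
  structure(list(mean = mu, modes = modes,
                 eigenvalues = (sv$d[seq_len(n_modes)]^2) / (K - 1),
                 loadings = loadings,
                 subject_ids = rownames(x) %||% sprintf("s%03d", seq_len(K)),
                 labels = shape_labels(x)),
            class = "rv_pca")
}

#' @export
print.rv_pca <- function(x, ...) {
  cat(sprintf("<rv_pca> %d shapes, %d coordinates, %d modes; %d modes explain 99%% variance\n",
              nrow(x$loadings), length(x$mean), length(x$eigenvalues),
              num_modes_for_variance(x, 0.99)))
  invisible(x)
}

#' Tidy PCA eigenvalue spectrum
#'
#' @param x an `rv_pca`.
#' @param ... unused.
#' @return tibble with mode, eigenvalue, prop_variance, cum_variance.
#' @export
tidy.rv_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(mode = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 prop_variance = if (tot > 0) x$eigenvalues / tot else 0,
                 cum_variance = if (tot > 0) cumsum(x$eigenvalues) / tot else 0)
}

#' @export
glance.rv_pca <- function(x, ...) {
  tibble::tibble(n_shapes = nrow(x$loadings), n_coords = length(x$mean),
                 n_modes = length(x$eigenvalues),
                 total_variance = sum(x$eigenvalues),
                 n_modes_99 = num_modes_for_variance(x, 0.99))
}

#' Per-subject PCA loadings as a tibble
#'
#' @param model an `rv_pca`.
#' @param n_modes number of leading modes to keep (default all).
#' @return tibble with subject_id, group, subgroup and columns `s1..sm`.
#' @export
pca_loadings <- function(model, n_modes = NULL) {
  m <- n_modes %||% ncol(model$loadings)
  L <- model$loadings[, seq_len(m), drop = FALSE]
  colnames(L) <- paste0("s", seq_len(m))
  lab <- model$labels %||% tibble::tibble(subject_id = model$subject_ids,
                                          group = NA_character_, subgroup = "none")
  dplyr::bind_cols(lab, tibble::as_tibble(L))
}

#' Number of modes explaining a variance fraction
#'
#' @param model an `rv_pca`.
#' @param fraction target cumulative variance share (default 0.99).
#' @return smallest mode count whose cumulative eigenvalue share reaches the
#'   fraction; 0 if all eigenvalues are zero.
#' @export
num_modes_for_variance <- function(model, fraction = 0.99) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  tot <- sum(model$eigenvalues)
  if (tot <= 0) return(0L)
  as.integer(which(cumsum(model$eigenvalues) / tot >= fraction - 1e-12)[1])
}

#' Group mean shape vector
#'
#' Arithmetic mean of a group's rows of the shape matrix (the average
#' correspondence particle locations).
#'
#' @param x an `rv_shape_matrix`.
#' @param group group label to average over.
#' @return numeric vector of length 3M.
#' @export
mean_shape <- function(x, group) {
  lab <- shape_labels(x)
  rows <- which(lab$group == group)
  if (length(rows) == 0) abort(sprintf("group '%s' has no members", group))
  colMeans(unclass(x)[rows, , drop = FALSE])
}

#' Reconstruct a shape vector from loadings
#'
#' @param model an `rv_pca`.
#' @param loading coefficient vector (length <= number of modes).
#' @return `mean + sum_j loading_j * mode_j`, a 3M vector.
#' @export
reconstruct <- function(model, loading) {
  m <- length(loading)
  if (m > ncol(model$modes)) {
    abort(sprintf("loading has %d coefficients but the model has only %d modes",
                  m, ncol(model$modes)))
  }
  model$mean + as.vector(model$modes[, seq_len(m), drop = FALSE] %*% loading)
}

#' Export mode-extreme shapes as particle files
#'
#' Writes the mean and the mean +/- `n_sd` standard deviations along each of
#' the first `n_modes` modes, for mode-shape visualization.
#'
#' @param model an `rv_pca`.
#' @param dir output directory.
#' @param n_modes,n_sd how many modes and how far along each (default 2 sd).
#' @return invisibly, the written file paths.
#' @export
export_mode_shapes <- function(model, dir, n_modes = 4, n_sd = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_modes <- min(n_modes, length(model$eigenvalues))
  to_pts <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  paths <- file.path(dir, "mean.particles")
  write_particle_file(to_pts(model$mean), paths)
  for (j in seq_len(n_modes)) {
    s <- n_sd * sqrt(model$eigenvalues[j])
    for (sg in c(-1, 1)) {
      l <- numeric(j); l[j] <- sg * s
      f <- file.path(dir, sprintf("mode%02d_%s%gsd.particles", j,
                                  if (sg < 0) "minus" else "plus", n_sd))
      write_particle_file(to_pts(reconstruct(model, l)), f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Scree plot of a PCA shape model
#'
#' @param object an `rv_pca`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rv_pca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prop_variance), fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_variance), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cum_variance), colour = "firebrick") +
    ggplot2::labs(x = "PCA mode", y = "variance share (bars) / cumulative (line)") +
    ggplot2::theme_minimal()
}
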