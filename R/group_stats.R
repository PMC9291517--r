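# Group-level shape statistics: linear-discrimination shape scores with the
# -1/+1 normalization convention and per-group Gaussian density fits, and
# per-correspondence-point Hotelling T-squared significance maps with FDR
# control.

#' Linear-discrimination shape scores between two groups
#'
#' The discrimination axis is the difference vector `d = mean(B) - mean(A)`
#' between the two group mean shapes. Every subject (members of other groups
#' included) is projected onto `d` by a dot product on overall-centered shape
#' vectors; the affine normalization then maps the projection of the group-A
#' mean to -1 and of the group-B mean to +1 (in the TR analyses, the
#' TR-containing group is A). Centering shifts all raw scores by a common
#' constant that the affine map absorbs, so normalized scores are unchanged
#' by it. A univariate Gaussian is fitted to each group's normalized scores
#' by moment matching (sample mean and sd).
#'
#' @param x an `rv_shape_matrix`.
#' @param group_minus group label mapped to -1 (e.g. `"tr"`).
#' @param group_plus group label mapped to +1.
#' @return an `rv_ldv`: list with `scores` tibble (subject_id, group,
#'   subgroup, raw, score), `gaussians` tibble (group, mean, sd), the
#'   difference vector `d`, and the convention.
#' @export
ldv_scores <- function(x, group_minus, group_plus) {
  lab <- shape_labels(x)
  mu_a <- mean_shape(x, group_minus)
  mu_b <- mean_shape(x, group_plus)
  d <- mu_b - mu_a
  if (sqrt(sum(d^2)) < 1e-12) {
    abort("the two group mean shapes are identical; no discrimination axis exists")
  }
  center <- colMeans(unclass(x))
  raw <- as.vector(sweep(unclass(x), 2, center) %*% d)
  ra <- sum((mu_a - center) * d)
  rb <- sum((mu_b - center) * d)
  score <- -1 + 2 * (raw - ra) / (rb - ra)  # strictly increasing since rb - ra = |d|^2 > 0
  scores <- tibble::tibble(subject_id = lab$subject_id, group = lab$group,
                           subgroup = lab$subgroup %||% "none",
                           raw = raw, score = score)
  gaussians <- scores |>
    dplyr::filter(.data$group %in% c(group_minus, group_plus)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$score), sd = stats::sd(.data$score),
                     n = dplyr::n(), .groups = "drop")
  structure(list(scores = scores, gaussians = gaussians, d = d,
                 convention = c(minus = group_minus, plus = group_plus)),
            class = "rv_ldv")
}

#' @export
print.rv_ldv <- function(x, ...) {
  cat(sprintf("<rv_ldv> %s -> -1, %s -> +1; %d subjects scored\n",
              x$convention["minus"], x$convention["plus"], nrow(x$scores)))
  print(x$gaussians)
  invisible(x)
}

#' @export
tidy.rv_ldv <- function(x, ...) x$scores

#' @export
glance.rv_ldv <- function(x, ...) {
  tidyr::pivot_wider(x$gaussians, names_from = "group",
                     values_from = c("mean", "sd", "n")) |>
    dplyr::mutate(overlap = overlap_fraction(x))
}

#' Fraction of subjects in the score-overlap region
#'
#' The overlap region is the intersection of the two groups' normalized
#' score ranges `[max of the two minima, min of the two maxima]`; the
#' returned value is the fraction of the two groups' subjects falling inside
#' it (0 when the ranges are disjoint). This range-intersection reading is
#' one explicit interpretation of score-distribution overlap.
#'
#' @param result an `rv_ldv` whose two groups have >= 2 scored members each.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(result) {
  sc <- dplyr::filter(result$scores,
                      .data$group %in% result$convention)
  by_g <- split(sc$score, sc$group)
  if (any(lengths(by_g) < 2)) abort("both groups need >= 2 scored members")
  lo <- max(vapply(by_g, min, numeric(1)))
  hi <- min(vapply(by_g, max, numeric(1)))
  if (lo > hi) return(0)
  mean(sc$score >= lo & sc$score <= hi)
}

#' Shape-score densities (LDV plot)
#'
#' Normalized scores as a rug plus the fitted per-group Gaussian densities,
#' with the group means pinned at -1 and +1.
#'
#' @param object an `rv_ldv`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rv_ldv <- function(object, ...) {
  sc <- dplyr::filter(object$scores, .data$group %in% object$convention)
  grid <- seq(min(sc$score) - 0.5, max(sc$score) + 0.5, length.out = 300)
  dens <- object$gaussians |>
    dplyr::rowwise() |>
    dplyr::reframe(group = .data$group, score = grid,
                   density = stats::dnorm(grid, .data$mean, .data$sd))
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$score, colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$density)) +
    ggplot2::geom_rug(data = sc, ggplot2::aes(x = .data$score), sides = "b") +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 3, colour = "grey50") +
    ggplot2::labs(x = "shape-based score", y = "PDF") +
    ggplot2::theme_minimal()
}

#' Per-point Hotelling T-squared significance map
#'
#' For every correspondence point, a two-sample Hotelling T-squared test on
#' its 3D coordinates across the two groups:
#' `T2 = (n1 n2 / (n1 + n2)) * (xbar1 - xbar2)' S^-1 (xbar1 - xbar2)` with
#' the pooled covariance `S` ridge-regularized by `1e-6` mm^2. P-values come
#' from the `F(3, n1 + n2 - 4)` transform (or a label-permutation null when
#' `p_method = "permutation"`), and are FDR-adjusted by the
#' Benjamini-Hochberg step-up procedure; significance is adjusted p < 0.05.
#'
#' @param particles an `rv_particles`.
#' @param labels tibble with subject_id and group (e.g. cohort manifest).
#' @param group_a,group_b the two groups compared (>= 2 members each and
#'   `n1 + n2 >= 5` for the F transform).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param p_method `"f"` (parametric, default) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param seed seed for the permutation null.
#' @return an `rv_sigmap`: tibble with point, t2, p_raw, p_adj, significant,
#'   plus attributes `group_sizes` and `mean_points` (per-point grand means,
#'   for plotting).
#' @export
hotelling_map <- function(particles, labels, group_a, group_b, alpha = 0.05,
                          p_method = c("f", "permutation"), n_perm = 1000,
                          seed = 1L) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(particles, "rv_particles"))
  labels <- tibble::as_tibble(labels)
  ord <- match(particles$subject_ids, labels$subject_id)
  grp <- labels$group[ord]
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  n1 <- length(ia); n2 <- length(ib)
  if (n1 < 2 || n2 < 2) abort("both groups need at least 2 subjects")
  if (n1 + n2 < 5) abort("need n1 + n2 >= 5 for the F transform")
  M <- particles$M
  t2_for <- function(ia, ib) {
    vapply(seq_len(M), function(j) {
      x1 <- particles$points[ia, j, , drop = TRUE]
      x2 <- particles$points[ib, j, , drop = TRUE]
      d <- colMeans(x1) - colMeans(x2)
      S <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2) +
        diag(1e-6, 3)
      tryCatch((n1 * n2 / (n1 + n2)) * sum(d * solve(S, d)),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  t2 <- t2_for(ia, ib)
  nu <- n1 + n2 - 2
  fstat <- (nu - 3 + 1) / (3 * nu) * t2
  p_raw <- stats::pf(fstat, 3, nu - 2, lower.tail = FALSE)
  if (p_method == "permutation") {
    set.seed(seed)
    pool <- c(ia, ib)
    exceed <- rep(1, M)
    for (b in seq_len(n_perm)) {
      pa <- sample(pool)
      t2b <- t2_for(pa[seq_len(n1)], pa[-seq_len(n1)])
      exceed <- exceed + (t2b >= t2)
    }
    p_raw <- exceed / (n_perm + 1)
  }
  p_raw[is.na(p_raw)] <- 1  # singular even after ridge: flagged, p = 1
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  res <- tibble::tibble(point = seq_len(M), t2 = ifelse(is.na(t2), 0, t2),
                        p_raw = p_raw, p_adj = p_adj,
                        significant = p_adj < alpha)
  attr(res, "group_sizes") <- c(n1 = n1, n2 = n2)
  attr(res, "mean_points") <- apply(particles$points[c(ia, ib), , , drop = FALSE],
                                    c(2, 3), mean)
  class(res) <- c("rv_sigmap", class(res))
  res
}

#' Per-point mean-difference displacement arrows
#'
#' The per-point displacement `mean(B) - mean(A)` with magnitudes, for
#' arrow/magnitude renderings of group shape differences. The squared
#' magnitudes sum to the squared norm of the LDV difference vector.
#'
#' @param x an `rv_shape_matrix`.
#' @param group_a,group_b group labels.
#' @return tibble with point, dx, dy, dz, magnitude.
#' @export
mean_difference_arrows <- function(x, group_a, group_b) {
  d <- mean_shape(x, group_b) - mean_shape(x, group_a)
  D <- matrix(d, ncol = 3, byrow = TRUE)
  tibble::tibble(point = seq_len(nrow(D)), dx = D[, 1], dy = D[, 2], dz = D[, 3],
                 magnitude = sqrt(rowSums(D^2)))
}

#' Significance-map plot
#'
#' Scatter of per-point grand-mean positions in two projection planes,
#' colored by -log10 adjusted p, significant points emphasized.
#'
#' @param object an `rv_sigmap`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rv_sigmap <- function(object, ...) {
  mp <- attr(object, "mean_points")
  d <- dplyr::bind_rows(
    tibble::tibble(u = mp[, 1], v = mp[, 3], plane = "x-z",
                   p_adj = object$p_adj, significant = object$significant),
    tibble::tibble(u = mp[, 2], v = mp[, 3], plane = "y-z",
                   p_adj = object$p_adj, significant = object$significant))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$u, y = .data$v,
                                  colour = -log10(pmax(.data$p_adj, 1e-16)),
                                  shape = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = "-log10 p_adj") +
    ggplot2::labs(x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

#' Export a significance map and arrows as CSV
#'
#' @param sigmap an `rv_sigmap`.
#' @param arrows tibble from [mean_difference_arrows()] (same point order).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_significance_csv <- function(sigmap, arrows, path) {
  out <- dplyr::left_join(tibble::as_tibble(sigmap), arrows, by = "point")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
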