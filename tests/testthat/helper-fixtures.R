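# Shared fixtures, all generated in code.

# radius-r sphere as an rv_surface on an n x n parameter grid
sphere_surface <- function(r = 10, n = 64) {
  structure(list(theta = (seq_len(n) - 0.5) * pi / n,
                 phi = (seq_len(n) - 1) * 2 * pi / n,
                 r = matrix(r, n, n), pose = diag(3),
                 group = "template", subgroup = "none"),
            class = "rv_surface")
}

# simulated loadings table: centered columns with decaying scales, optional
# informative first mode (label = median split of s1), like PCA loadings of a
# cohort with one dominant discriminative mode
simulate_loadings <- function(seed, informative = TRUE, n = 40, p = 31) {
  set.seed(seed)
  S <- matrix(rnorm(n * p), n, p)
  S <- sweep(S, 2, exp(-0.15 * (0:(p - 1))), "*")
  S <- scale(S, center = TRUE, scale = FALSE)
  y <- if (informative) as.integer(S[, 1] > stats::median(S[, 1])) else
    sample(rep(0:1, each = n / 2))
  df <- tibble::as_tibble(as.data.frame(S))
  names(df) <- paste0("s", seq_len(p))
  df$subject_id <- sprintf("x%03d", seq_len(n))
  df$group <- ifelse(y == 1, "tr", "control")
  df$subgroup <- "none"
  df
}

# small three-group loadings cohort for SMOTE tests
simulate_three_groups <- function(seed, n_control = 20, n_tr = 5, n_healthy = 4, p = 6) {
  set.seed(seed)
  n <- n_control + n_tr + n_healthy
  grp <- c(rep("control", n_control), rep("tr", n_tr), rep("healthy", n_healthy))
  shift <- c(control = 0, tr = 3, healthy = -3)
  S <- matrix(rnorm(n * p), n, p)
  S[, 1] <- S[, 1] + shift[grp]
  df <- tibble::as_tibble(as.data.frame(S))
  names(df) <- paste0("s", seq_len(p))
  df$subject_id <- sprintf("g%03d", seq_len(n))
  df$group <- grp
  df$subgroup <- "none"
  df
}

# tiny two-group particle cohort built from integer coordinates (3M = 6)
toy_shape_matrix <- function() {
  pts <- array(0, dim = c(4, 2, 3))
  pts[1, , ] <- rbind(c(0, 0, 0), c(2, 0, 0))
  pts[2, , ] <- rbind(c(0, 2, 0), c(2, 2, 0))
  pts[3, , ] <- rbind(c(4, 0, 0), c(6, 0, 0))
  pts[4, , ] <- rbind(c(4, 2, 0), c(6, 2, 0))
  ps <- new_particle_system(pts, sprintf("t%d", 1:4))
  lab <- tibble::tibble(subject_id = sprintf("t%d", 1:4),
                        group = c("tr", "tr", "control", "control"),
                        subgroup = "none")
  shape_matrix(ps, lab)
}
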