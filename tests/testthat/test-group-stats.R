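test_that("LDV scores pin group means at -1/+1 with hand-checked arithmetic", {
  sm <- toy_shape_matrix()
  ldv <- ldv_scores(sm, "tr", "control")
  X <- unclass(sm)
  mu_a <- colMeans(X[1:2, ]); mu_b <- colMeans(X[3:4, ])
  d <- mu_b - mu_a
  ctr <- colMeans(X)
  raw_hand <- as.vector(sweep(X, 2, ctr) %*% d)
  expect_equal(ldv$scores$raw, raw_hand, tolerance = 1e-12)
  ra <- sum((mu_a - ctr) * d); rb <- sum((mu_b - ctr) * d)
  expect_equal(ldv$scores$score, -1 + 2 * (raw_hand - ra) / (rb - ra),
               tolerance = 1e-12)
  # group means map exactly to -1 and +1; the midpoint to 0
  expect_equal(mean(ldv$scores$score[1:2]), -1, tolerance = 1e-10)
  expect_equal(mean(ldv$scores$score[3:4]), 1, tolerance = 1e-10)
  mid_raw <- sum(((mu_a + mu_b) / 2 - ctr) * d)
  expect_equal(-1 + 2 * (mid_raw - ra) / (rb - ra), 0, tolerance = 1e-10)
  # identical group means are rejected
  same <- sm; attr(same, "labels")$group <- c("tr", "control", "tr", "control")
  X2 <- unclass(sm); X2[3, ] <- X2[1, ]; X2[4, ] <- X2[2, ]
  sm2 <- structure(X2, labels = attr(sm, "labels"),
                   class = class(sm))
  expect_error(ldv_scores(sm2, "tr", "control"), "identical")
})

test_that("LDV scores are invariant to a common rigid translation", {
  sm <- toy_shape_matrix()
  ldv <- ldv_scores(sm, "tr", "control")
  shift <- rep(c(5, -3, 2), 2)
  smT <- structure(sweep(unclass(sm), 2, -shift, "-"),
                   labels = attr(sm, "labels"), class = class(sm))
  ldvT <- ldv_scores(smT, "tr", "control")
  expect_equal(ldv$scores$score, ldvT$scores$score, tolerance = 1e-10)
})

test_that("every subject is scored, including members of other groups", {
  spec <- cohort_spec(seed = 14, resolution = 48)
  coh <- generate_cohort(spec, voxelize_masks = FALSE)
  ps <- attach_ground_truth(coh, M = 64)
  sm <- shape_matrix(ps, coh$manifest)
  ldv <- ldv_scores(sm, "tr", "control")
  expect_equal(nrow(ldv$scores), 54)
  expect_equal(ldv$gaussians$mean[ldv$gaussians$group == "tr"], -1, tolerance = 1e-10)
  expect_equal(ldv$gaussians$mean[ldv$gaussians$group == "control"], 1, tolerance = 1e-10)
  expect_true(all(ldv$gaussians$sd > 0))
})

test_that("overlap fraction implements range intersection", {
  mk <- function(a, b) {
    structure(list(
      scores = tibble::tibble(
        subject_id = seq_len(length(a) + length(b)),
        group = c(rep("A", length(a)), rep("B", length(b))),
        subgroup = "none", raw = 0, score = c(a, b)),
      convention = c(minus = "A", plus = "B")), class = "rv_ldv")
  }
  expect_equal(overlap_fraction(mk(c(-1, 0, 1), c(-1, 0, 1))), 1)
  expect_equal(overlap_fraction(mk(c(-2, -1), c(1, 2))), 0)
  expect_equal(overlap_fraction(mk(c(-1.0, -0.2), c(-0.4, 1.0))), 0.5)
  expect_error(overlap_fraction(mk(-1, c(0, 1))), ">= 2")
})

test_that("Hotelling map nullifies duplicate cohorts and localizes a bulge", {
  # duplicated halves: identical group means per point -> T2 = 0, p = 1
  set.seed(4)
  half <- array(rnorm(3 * 16 * 3), dim = c(3, 16, 3))
  pts <- array(0, dim = c(6, 16, 3))
  pts[1:3, , ] <- half; pts[4:6, , ] <- half
  ps <- new_particle_system(pts, sprintf("s%d", 1:6))
  lab <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                        group = rep(c("A", "B"), each = 3), subgroup = "none")
  sig <- hotelling_map(ps, lab, "A", "B")
  expect_true(all(sig$t2 < 1e-10))
  expect_true(all(sig$p_raw > 1 - 1e-10))
  expect_true(all(sig$p_adj >= sig$p_raw - 1e-12))
  expect_false(any(sig$significant))

  # bulge-only TR cohort: significant points concentrate on the free wall
  spec <- cohort_spec(group_sizes = c(healthy = 0, control = 15, tr = 15),
                      subgroup_fractions = list(),
                      deformation = deformation_params(bulge_amp = 5,
                        apex_blunt_amp = 0, base_width_amp = 0,
                        midwall_pinch_amp = 0),
                      noise_sd = 1, seed = 15, resolution = 48)
  coh <- generate_cohort(spec, voxelize_masks = FALSE)
  psc <- attach_ground_truth(coh, M = 128)
  sigc <- hotelling_map(psc, coh$manifest, "control", "tr")
  expect_gt(sum(sigc$significant), 0)
  fw <- as.vector(surface_patches(coh$base)$free_wall)[attr(psc, "grid_index")]
  expect_gt(mean(fw[sigc$significant]), 0.7)
  expect_error(hotelling_map(psc, coh$manifest, "control", "absent"), "2 subjects")
})

test_that("permutation p-values broadly agree with the F transform", {
  spec <- cohort_spec(group_sizes = c(healthy = 0, control = 8, tr = 8),
                      subgroup_fractions = list(),
                      deformation = deformation_params(bulge_amp = 4,
                        apex_blunt_amp = 0, base_width_amp = 0,
                        midwall_pinch_amp = 0),
                      noise_sd = 1, seed = 16, resolution = 48)
  coh <- generate_cohort(spec, voxelize_masks = FALSE)
  ps <- attach_ground_truth(coh, M = 32)
  f_map <- hotelling_map(ps, coh$manifest, "control", "tr")
  p_map <- hotelling_map(ps, coh$manifest, "control", "tr",
                         p_method = "permutation", n_perm = 400, seed = 2)
  expect_equal(f_map$t2, p_map$t2)
  expect_gt(stats::cor(f_map$p_raw, p_map$p_raw, method = "spearman"), 0.9)
})

test_that("mean-difference arrows integrate to the LDV difference vector", {
  sm <- toy_shape_matrix()
  arr <- mean_difference_arrows(sm, "tr", "control")
  ldv <- ldv_scores(sm, "tr", "control")
  expect_equal(sum(arr$magnitude^2), sum(ldv$d^2), tolerance = 1e-12)
  # identical groups: zero arrows
  lab <- attr(sm, "labels")
  X <- unclass(sm); X[3:4, ] <- X[1:2, ]
  smI <- structure(X, labels = lab, class = class(sm))
  expect_true(all(mean_difference_arrows(smI, "tr", "control")$magnitude < 1e-12))
  # pure translation between groups: every arrow equals the translation
  X2 <- unclass(sm); X2[3:4, ] <- X2[1:2, ] + rep(c(1, 2, 3), 2)[col(X2[1:2, ])]
  smT <- structure(X2, labels = lab, class = class(sm))
  arrT <- mean_difference_arrows(smT, "tr", "control")
  expect_equal(unname(as.matrix(arrT[, c("dx", "dy", "dz")])),
               matrix(c(1, 2, 3), 2, 3, byrow = TRUE))
})

test_that("LDV raw-score separation grows with the bulge amplitude", {
  seps <- vapply(c(1, 3, 5), function(amp) {
    spec <- cohort_spec(group_sizes = c(healthy = 0, control = 12, tr = 12),
                        subgroup_fractions = list(),
                        deformation = deformation_params(bulge_amp = amp,
                          apex_blunt_amp = 0, base_width_amp = 0,
                          midwall_pinch_amp = 0),
                        noise_sd = 1, seed = 17, resolution = 48)
    coh <- generate_cohort(spec, voxelize_masks = FALSE)
    ps <- attach_ground_truth(coh, M = 64)
    ldv <- ldv_scores(shape_matrix(ps, coh$manifest), "tr", "control")
    by_g <- split(ldv$scores$raw[ldv$scores$group %in% c("tr", "control")],
                  ldv$scores$group[ldv$scores$group %in% c("tr", "control")])
    abs(mean(by_g$tr) - mean(by_g$control)) /
      sqrt((stats::var(by_g$tr) + stats::var(by_g$control)) / 2)
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})
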