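test_that("PCA handles degenerate and rank-1 cohorts exactly", {
  X <- matrix(rep(c(1, 2, 3, 4, 5, 6), 3), nrow = 3, byrow = TRUE)
  pca0 <- fit_pca(X)
  expect_true(all(pca0$eigenvalues < 1e-20))
  expect_true(all(abs(pca0$loadings) < 1e-10))

  # three collinear shapes mu, mu + d, mu - d: one nonzero mode, loadings 0, +|d|, -|d|
  mu <- c(1, 1, 1, 1, 1, 1)
  d <- c(1, 0, 2, 0, -2, 0)
  X1 <- rbind(mu, mu + d, mu - d)
  pca1 <- fit_pca(X1)
  expect_equal(sum(pca1$eigenvalues > 1e-12), 1)
  l1 <- pca1$loadings[, 1]
  expect_equal(abs(l1), c(0, sqrt(sum(d^2)), sqrt(sum(d^2))), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(l1[2], -l1[3], tolerance = 1e-10, ignore_attr = TRUE)
  # reconstruction identities
  expect_equal(reconstruct(pca1, numeric(0)), pca1$mean, ignore_attr = TRUE)
  for (i in 1:3) {
    expect_equal(reconstruct(pca1, pca1$loadings[i, ]), X1[i, ],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # +/- 1 sd along mode 1 of this rank-1 cohort hits the two extreme shapes:
  # eigenvalue = (0 + |d|^2 + |d|^2) / (K - 1) = |d|^2, so sd = |d|
  s <- sqrt(pca1$eigenvalues[1])
  expect_equal(s, sqrt(sum(d^2)), tolerance = 1e-10)
  ext <- rbind(reconstruct(pca1, s * sign(l1[2])),
               reconstruct(pca1, -s * sign(l1[2])))
  expect_equal(ext[1, ], mu + d, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ext[2, ], mu - d, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(reconstruct(pca1, rep(0, 10)), "modes")
  expect_error(fit_pca(X1[1, , drop = FALSE]), "at least 2")
})

test_that("PCA modes are orthonormal and variance is conserved", {
  set.seed(6)
  X <- matrix(rnorm(12 * 30), 12, 30)
  pca <- fit_pca(X)
  G <- crossprod(pca$modes)
  expect_equal(G, diag(ncol(pca$modes)), tolerance = 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_true(all(pca$eigenvalues >= 0))
  # total variance equals mean squared distance to the mean (per K-1)
  Yc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(pca$eigenvalues), sum(Yc^2) / (nrow(X) - 1), tolerance = 1e-10)
  # full-mode reconstruction reproduces every row
  for (i in c(1, 7)) {
    expect_equal(reconstruct(pca, pca$loadings[i, ]), X[i, ],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("mode counting follows cumulative eigenvalue shares", {
  fake <- list(eigenvalues = c(4, 3, 2, 1))
  expect_equal(num_modes_for_variance(fake, 0.99), 4)
  expect_equal(num_modes_for_variance(fake, 0.4), 1)
  expect_equal(num_modes_for_variance(fake, 0.9), 3)
  expect_equal(num_modes_for_variance(list(eigenvalues = c(5, 0, 0)), 0.5), 1)
  expect_equal(num_modes_for_variance(list(eigenvalues = c(0, 0)), 0.99), 0)
  expect_error(num_modes_for_variance(fake, 0), "fraction")
})

test_that("group mean shapes behave linearly", {
  sm <- toy_shape_matrix()
  expect_equal(mean_shape(sm, "tr"), colMeans(unclass(sm)[1:2, ]))
  expect_error(mean_shape(sm, "absent"), "no members")
  one <- shape_matrix(new_particle_system(array(1:6, c(1, 2, 3)), "a"),
                      tibble::tibble(subject_id = "a", group = "g", subgroup = "none"))
  expect_equal(mean_shape(one, "g"), as.vector(unclass(one)[1, ]))
})

test_that("mode-1 loadings recover a varying bulge amplitude", {
  base <- generate_base_surface(48)
  set.seed(11)
  amps <- runif(15, 0, 6)
  surfaces <- lapply(amps, function(a) {
    apply_group_deformation(base, "tr",
      params = deformation_params(bulge_amp = a, apex_blunt_amp = 0, base_width_amp = 0),
      noise_sd = 0.2)
  })
  cohort <- structure(list(surfaces = surfaces, base = base,
                           manifest = tibble::tibble(
                             subject_id = sprintf("s%02d", seq_along(amps)),
                             group = "tr", subgroup = "none", seed = 11)),
                      class = "rv_cohort")
  ps <- attach_ground_truth(cohort, M = 128)
  pca <- fit_pca(shape_matrix(ps, cohort$manifest))
  expect_gt(abs(stats::cor(pca$loadings[, 1], amps)), 0.9)
})

test_that("tidy/glance/loadings accessors are consistent", {
  set.seed(3)
  X <- matrix(rnorm(8 * 12), 8, 12)
  pca <- fit_pca(X)
  td <- tidy(pca)
  expect_equal(td$cum_variance[nrow(td)], 1, tolerance = 1e-10)
  gl <- glance(pca)
  expect_equal(gl$n_modes_99, num_modes_for_variance(pca, 0.99))
  lo <- pca_loadings(pca, 3)
  expect_equal(names(lo), c("subject_id", "group", "subgroup", "s1", "s2", "s3"))
  expect_equal(as.matrix(lo[, 4:6]), pca$loadings[, 1:3], ignore_attr = TRUE)
})

test_that("mode-extreme shapes export as valid particle files", {
  set.seed(9)
  X <- matrix(rnorm(6 * 30), 6, 30)  # 10 particles
  pca <- fit_pca(X)
  dir <- withr::local_tempdir()
  paths <- export_mode_shapes(pca, dir, n_modes = 2)
  expect_true(all(file.exists(file.path(dir, "mean.particles"))))
  for (f in list.files(dir, full.names = TRUE)) {
    expect_silent(pts <- read_particle_file(f, expected_m = 10))
  }
})
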