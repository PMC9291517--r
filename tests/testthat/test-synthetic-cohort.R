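test_that("base surface is a valid deterministic star-shaped template", {
  s1 <- generate_base_surface(64)
  s2 <- generate_base_surface(64)
  expect_true(all(s1$r > 0))
  expect_identical(s1$r, s2$r)
  expect_error(generate_base_surface(8), "at least 16")
})

test_that("analytic surface volume matches voxelized volume within 2%", {
  base <- generate_base_surface(96)
  v_analytic <- surface_volume(base)
  m <- voxelize(base, spacing = 1)
  v_voxel <- sum(m$voxels) * 1
  expect_lt(abs(v_voxel - v_analytic) / v_analytic, 0.02)
})

test_that("group deformations have the stated amplitude, location and identity case", {
  base <- generate_base_surface(96)
  zero <- deformation_params(0, 0, 0, 0)
  same <- apply_group_deformation(base, "tr", params = zero)
  expect_equal(same$r, base$r)
  bulge <- apply_group_deformation(base, "tr",
    params = deformation_params(bulge_amp = 5, apex_blunt_amp = 0,
                                base_width_amp = 0))
  dif <- bulge$r - base$r
  expect_equal(max(dif), 5, tolerance = 0.01)
  am <- which(dif == max(dif), arr.ind = TRUE)
  expect_true(surface_patches(base)$free_wall[am])
  # comorbid control displaces the mid free wall inward
  ctrl <- apply_group_deformation(base, "control",
    params = deformation_params(midwall_pinch_amp = 2.5))
  expect_lt(min(ctrl$r - base$r), -2.4)
  expect_true(all(ctrl$r - base$r <= 1e-12))
  # over-large deformation errors instead of producing a non-star shape
  expect_error(apply_group_deformation(base, "control",
    params = deformation_params(midwall_pinch_amp = 1e3)), "non-positive")
})

test_that("subject noise field has the stated pointwise scale", {
  base <- generate_base_surface(64)
  set.seed(5)
  rms <- replicate(100, {
    a <- apply_group_deformation(base, "healthy", noise_sd = 1)
    b <- apply_group_deformation(base, "healthy", noise_sd = 1)
    sqrt(mean((a$r - b$r)^2))
  })
  # two independent unit-sd fields differ by an RMS of sqrt(2)
  expect_equal(mean(rms), sqrt(2), tolerance = 0.05)
  expect_error(apply_group_deformation(base, "healthy", noise_sd = -1), ">= 0")
})

test_that("voxelization respects volume conservation and degenerate contracts", {
  sph <- sphere_surface(10)
  m1 <- voxelize(sph, spacing = 1)
  expect_equal(sum(m1$voxels), 4 / 3 * pi * 1000, tolerance = 0.03)
  m05 <- voxelize(sph, spacing = 0.5)
  expect_equal(sum(m05$voxels) / sum(m1$voxels), 8, tolerance = 0.03)
  expect_error(voxelize(sphere_surface(0.2), spacing = 1), "half a voxel")
  expect_error(voxelize(sph, spacing = 1, dims = 12), "exceeds the grid")
})

test_that("cohort generation is deterministic with the stated composition", {
  spec <- cohort_spec(seed = 42, resolution = 48)
  coh <- generate_cohort(spec, voxelize_masks = FALSE)
  expect_equal(nrow(coh$manifest), 54)
  expect_equal(as.vector(table(coh$manifest$group)[c("healthy", "control", "tr")]),
               c(6, 27, 21))
  sub <- table(coh$manifest$group, coh$manifest$subgroup)
  expect_equal(as.vector(sub["control", c("phtn", "chf", "other")]), c(4, 12, 11))
  expect_equal(as.vector(sub["tr", c("phtn", "chf", "other")]), c(3, 9, 9))

  spec_small <- cohort_spec(group_sizes = c(healthy = 0, control = 4, tr = 0),
                            subgroup_fractions = list(), seed = 1,
                            resolution = 48, grid_dims = 72)
  coh_small <- generate_cohort(spec_small)
  expect_equal(nrow(coh_small$manifest), 4)
  expect_true(all(coh_small$manifest$group == "control"))
  coh_small2 <- generate_cohort(spec_small)
  expect_identical(lapply(coh_small$masks, `[[`, "voxels"),
                   lapply(coh_small2$masks, `[[`, "voxels"))
})

test_that("TR free wall bulges outward relative to controls in expectation", {
  spec <- cohort_spec(group_sizes = c(healthy = 0, control = 20, tr = 20),
                      subgroup_fractions = list(),
                      deformation = deformation_params(bulge_amp = 5),
                      noise_sd = 0.5, seed = 13, resolution = 48)
  coh <- generate_cohort(spec, voxelize_masks = FALSE)
  fw <- surface_patches(coh$surfaces[[1]])$free_wall
  mean_fw <- vapply(coh$surfaces, function(s) mean(s$r[fw]), numeric(1))
  grp <- coh$manifest$group
  expect_gt(mean(mean_fw[grp == "tr"]) - mean(mean_fw[grp == "control"]), 0)
})

test_that("ground-truth correspondence points lie on the voxelized surface", {
  spec <- cohort_spec(group_sizes = c(healthy = 2, control = 0, tr = 0),
                      subgroup_fractions = list(), seed = 3, resolution = 64)
  coh <- generate_cohort(spec)
  dt <- signed_distance_transform(coh$masks[[1]])
  pts <- surface_points(coh$surfaces[[1]])
  d <- rvshape:::interp3(dt$values, dt$spacing, dt$origin, pts)
  expect_lt(max(abs(d)), dt$spacing / 2 + 1e-9)
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(group_sizes = c(healthy = -1, control = 2, tr = 2)), ">= 0")
  expect_error(cohort_spec(noise_sd = -0.1), ">= 0")
  expect_error(cohort_spec(voxel_spacing = 0), "positive")
  expect_error(cohort_spec(subgroup_fractions = list(control = c(phtn = 0.5, chf = 0.2, other = 0.2))),
               "sum to 1")
})

test_that("cohort masks and particles round-trip through disk formats", {
  spec <- cohort_spec(group_sizes = c(healthy = 2, control = 0, tr = 0),
                      subgroup_fractions = list(), seed = 8, resolution = 48)
  coh <- generate_cohort(spec)
  for (fmt in c("nifti", "metaimage")) {
    dir <- withr::local_tempdir()
    man <- write_cohort(coh, dir, format = fmt)
    expect_true(file.exists(file.path(dir, "manifest.csv")))
    back <- read_mask(man$file[1])
    expect_equal(back$voxels, coh$masks[[1]]$voxels)
    expect_equal(back$spacing, coh$masks[[1]]$spacing)
    pts <- read_particle_file(file.path(dir, paste0(man$subject_id[1], ".particles")))
    expect_equal(pts, surface_points(coh$surfaces[[1]]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})
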