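test_that("generated geometry honours the analytic shapes and constraints", {
  g <- small_grid()
  geom <- generate_geometry(g, small_config(), seed = 1)

  expect_equal(nrow(geom$marker_positions), 3L)
  analytic <- 4 / 3 * pi * prod(geom$erb_semi_axes)
  voxelised <- sum(geom$structure_masks$ERB) * voxel_volume_mm3(g)
  expect_lt(abs(voxelised - analytic) / analytic, 0.05)

  # ERB contained in rectum, CTV in PTV
  expect_false(any(geom$structure_masks$ERB & !geom$structure_masks$rectum))
  expect_false(any(geom$structure_masks$CTV & !geom$structure_masks$PTV))

  # same seed reproduces the geometry exactly; different seed moves markers
  geom2 <- generate_geometry(g, small_config(), seed = 1)
  expect_identical(geom$marker_positions, geom2$marker_positions)
  geom3 <- generate_geometry(g, small_config(), seed = 2)
  expect_false(identical(geom$marker_positions, geom3$marker_positions))
})

test_that("infeasible geometry configurations are rejected", {
  g <- small_grid()
  expect_error(
    generate_geometry(g, small_config(marker_min_separation_mm = 100)),
    class = "igrt_geometry_error")
  # ERB larger than the grid
  expect_error(
    generate_geometry(g, small_config(erb_semi_axes = c(80, 16, 10))),
    class = "igrt_bounds_error")
  err <- tryCatch(
    generate_geometry(g, small_config(erb_semi_axes = c(80, 16, 10))),
    igrt_bounds_error = function(e) e)
  expect_match(conditionMessage(err), "ERB")
})

test_that("sampled motion follows the hierarchical Gaussian model", {
  # degenerate parameters give exactly zero shifts
  zero <- sample_motion(motion_params(), 3, 5, seed = 1)
  expect_true(all(vapply(zero, function(s) all(s$shifts == 0), logical(1))))

  # sampling-theory oracle: SD over patients of per-patient means is
  # sqrt(Sigma^2 + sigma^2 / n_fractions)
  mp <- motion_params(group_mean = 0, sigma_systematic = 2.0,
                      sigma_random = 3.0)
  ser <- sample_motion(mp, 1000, 28, seed = 42)
  means <- t(vapply(ser, function(s) colMeans(s$shifts), numeric(3)))
  expected <- sqrt(2.0^2 + 3.0^2 / 28)
  for (ax in 1:3)
    expect_lt(abs(sd(means[, ax]) - expected) / expected, 0.10)

  # determinism
  ser2 <- sample_motion(mp, 10, 28, seed = 42)
  ser3 <- sample_motion(mp, 10, 28, seed = 42)
  expect_identical(lapply(ser2, `[[`, "shifts"), lapply(ser3, `[[`, "shifts"))

  expect_error(motion_params(sigma_systematic = -1), "non-negative")
})

test_that("per-fraction random error converges to its generative SD", {
  mp <- motion_params(sigma_systematic = 0, sigma_random = 2.0)
  ser <- sample_motion(mp, 500, 28, seed = 9)        # 14000 draws per axis
  pooled <- do.call(rbind, lapply(ser, `[[`, "shifts"))
  for (ax in 1:3)
    expect_lt(abs(sd(pooled[, ax]) - 2.0) / 2.0, 0.05)
})

test_that("rendered volumes translate the mobile structures exactly", {
  g <- mm_grid()
  geom <- generate_geometry(g, mm_config(), seed = 3)

  plan <- render_volume(geom, c(0, 0, 0), noise_sd = 0)
  same <- render_volume(geom, c(0, 0, 0), noise_sd = 0)
  expect_identical(plan$voxels, same$voxels)

  # 3 mm LR shift on a 1 mm grid is an integer-voxel translation
  shifted <- render_volume(geom, c(3, 0, 0), noise_sd = 0)
  erb_plan <- plan$voxels == geom$config$intensity_erb
  erb_shift <- shifted$voxels == geom$config$intensity_erb
  n <- g$shape[1]
  expect_identical(erb_shift[4:n, , ], erb_plan[1:(n - 3), , ])

  # ideal thresholding of a noise-free render finds exactly 3 markers
  lab <- label_components(plan$voxels > 1000)
  expect_identical(max(lab), 3L)

  # shifts that push a structure off the grid are rejected
  expect_error(render_volume(geom, c(40, 0, 0)), class = "igrt_bounds_error")
  # markers darker than background cannot be rendered meaningfully
  dark <- generate_geometry(g, mm_config(intensity_marker = 10), seed = 3)
  expect_error(render_volume(dark, c(0, 0, 0)), class = "igrt_render_error")
})

test_that("the synthetic dose grid covers the PTV and falls off outside", {
  g <- small_grid()
  geom <- generate_geometry(g, small_config(), seed = 1)
  dg <- generate_dose_grid(geom, prescription_gy = 50.4)
  expect_gte(min(dg$volume$voxels[geom$structure_masks$PTV]), 50.4)
  expect_lt(dg$volume$voxels[1, 1, 1], 0.10 * 50.4)
  # doubling the prescription doubles dose everywhere
  dg2 <- generate_dose_grid(geom, prescription_gy = 100.8,
                            n_fractions = 28L, dose_per_fraction_gy = 3.6)
  expect_equal(dg2$volume$voxels, 2 * dg$volume$voxels)
})

test_that("cohorts record applied shifts exactly and count their scans", {
  cohort <- generate_cohort(n_patients = 3, n_fractions = 4,
                            grid = small_grid(), config = small_config(),
                            noise_sd = 0, seed = 5)
  expect_identical(cohort$counts$n_cbct, 12L)
  expect_identical(cohort$counts$n_intrafraction_records, 24L)

  # recorded truth equals the applied displacement: the pre/post marker
  # coordinates are the planning markers plus the recorded shifts
  pt <- cohort$patients[[2]]
  for (f in 1:4) {
    expect_equal(pt$markers_pre[[f]],
                 sweep(pt$geometry$marker_positions, 2,
                       pt$inter_true$shifts[f, ], `+`))
    expect_equal(pt$markers_post[[f]] - pt$markers_pre[[f]],
                 matrix(pt$intra_true$shifts[f, ], 3, 3, byrow = TRUE),
                 ignore_attr = TRUE)
  }

  # determinism: identical seed reproduces the cohort's tables
  cohort2 <- generate_cohort(n_patients = 3, n_fractions = 4,
                             grid = small_grid(), config = small_config(),
                             noise_sd = 0, seed = 5)
  expect_equal(cohort$patients[[1]]$inter_true$shifts,
               cohort2$patients[[1]]$inter_true$shifts)
  v1 <- cohort_volume(cohort, 1, 2)
  v2 <- cohort_volume(cohort2, 1, 2)
  expect_identical(v1$voxels, v2$voxels)
})
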