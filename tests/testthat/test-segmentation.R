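test_that("marker segmentation recovers planted blob centroids", {
  g <- grid_spec(c(40L, 40L, 40L), 2)
  # 50 random placements of 3 blobs each; centroid error <= half a voxel
  set.seed(11)
  for (case in 1:50) {
    centers <- matrix(runif(9, -25, 25), 3, 3)
    while (min(dist(centers)) < 12)
      centers <- matrix(runif(9, -25, 25), 3, 3)
    vox <- array(0, g$shape)
    for (i in 1:3) vox <- plant_blob(vox, g, centers[i, ], 3.5, 100)
    ms <- segment_markers(image_volume(vox, g), high_threshold = 50)
    expect_identical(nrow(ms$centroids), 3L)
    # match by order along SI/LR/AP as the canonical ordering guarantees
    ord <- order(centers[, 2], centers[, 1], centers[, 3])
    expect_lt(max(abs(ms$centroids - centers[ord, ])), 0.5 * max(g$spacing))
  }
})

test_that("marker segmentation reports countable failures and exact cases", {
  g <- grid_spec(c(20L, 20L, 20L), 1, origin = c(0, 0, 0))
  empty <- image_volume(array(0, g$shape), g)
  err <- tryCatch(segment_markers(empty, high_threshold = 0.5),
                  igrt_marker_count_error = function(e) e)
  expect_s3_class(err, "igrt_marker_count_error")
  expect_identical(err$count, 0L)

  # single 3x3x3 blob centred on voxel (10,10,10), origin 0 -> centroid 9 mm
  # (voxel (1,1,1) sits at 0 mm, so voxel (10,10,10) is at 9 mm per axis)
  vox <- array(0, g$shape)
  vox[9:11, 9:11, 9:11] <- 10
  ms <- segment_markers(image_volume(vox, g), high_threshold = 5,
                        expected_count = 1L)
  expect_equal(unname(ms$centroids[1, ]), c(9, 9, 9))

  # fragments closer than one voxel (diagonal contact) are one marker;
  # a full one-voxel background gap keeps components distinct
  vox2 <- array(0, g$shape)
  vox2[5:6, 5:6, 5:6] <- 10
  vox2[7, 7, 7] <- 10   # corner-adjacent to the block
  ms2 <- segment_markers(image_volume(vox2, g), high_threshold = 5,
                         size_range = c(1, 100), expected_count = 1L)
  expect_identical(nrow(ms2$centroids), 1L)
  vox3 <- vox2; vox3[7, 7, 7] <- 0; vox3[8, 8, 8] <- 10
  ms3 <- segment_markers(image_volume(vox3, g), high_threshold = 5,
                         size_range = c(1, 100), expected_count = 2L)
  expect_identical(nrow(ms3$centroids), 2L)
})

test_that("ERB segmentation measures volume, displacement and picks the largest component", {
  g <- small_grid()
  geom <- generate_geometry(g, small_config(), seed = 2)
  plan <- render_volume(geom, c(0, 0, 0), noise_sd = 0)
  seg <- segment_erb(plan)
  analytic <- 4 / 3 * pi * prod(geom$erb_semi_axes)
  expect_lt(abs(seg$volume_mm3 - analytic) / analytic, 0.05)

  # planted +4 mm SI translation appears in the centroid
  shifted <- segment_erb(render_volume(geom, c(0, 4, 0), noise_sd = 0))
  expect_lt(abs((shifted$centroid_mm[2] - seg$centroid_mm[2]) - 4),
            0.5 * max(g$spacing))
  expect_lt(max(abs(shifted$centroid_mm[c(1, 3)] - seg$centroid_mm[c(1, 3)])),
            0.5 * max(g$spacing))

  # two air pockets: the larger one is selected
  vox <- array(100, g$shape)
  vox <- plant_blob(vox, g, c(-20, 0, 0), 12, -500)
  vox <- plant_blob(vox, g, c(25, 10, 5), 5, -500)
  two <- segment_erb(image_volume(vox, g), low_threshold = -100)
  expect_lt(max(abs(two$centroid_mm - c(-20, 0, 0))), 0.5)

  # nothing below threshold
  expect_error(segment_erb(image_volume(array(100, g$shape), g),
                           low_threshold = -100),
               class = "igrt_erb_not_found_error")
})

test_that("ERB volume is monotone non-increasing in the threshold", {
  g <- small_grid()
  geom <- generate_geometry(g, small_config(), seed = 2)
  vol <- render_volume(geom, c(0, 0, 0), noise_sd = 30, seed = 7)
  thresholds <- c(-700, -500, -300, -100)
  vols <- vapply(thresholds, function(th)
    segment_erb(vol, low_threshold = th)$volume_mm3, numeric(1))
  expect_true(all(diff(vols) >= 0))  # larger threshold admits more voxels
})

test_that("connected-component labelling agrees with flood fill", {
  set.seed(21)
  for (case in 1:8) {
    dm <- sample(6:16, 3, replace = TRUE)
    mask <- array(runif(prod(dm)) < 0.25, dm)
    for (conn in c(6L, 26L)) {
      got <- label_components(mask, connectivity = conn)
      ref <- flood_fill_labels(mask, connectivity = conn)
      expect_identical(max(got), max(ref))
      expect_true(same_partition(got, ref))
    }
  }
})

test_that("hole filling closes interior cavities only", {
  m <- array(FALSE, c(9, 9, 9))
  m[2:8, 2:8, 2:8] <- TRUE
  m[4:6, 4:6, 4:6] <- FALSE          # interior cavity
  filled <- fill_holes(m)
  expect_true(all(filled[2:8, 2:8, 2:8]))
  expect_identical(sum(filled), 343L)
  # an open notch reaching the border is not a hole
  m2 <- array(FALSE, c(9, 9, 9))
  m2[2:8, 2:8, 2:8] <- TRUE
  m2[4:6, 4:6, 1:6] <- FALSE
  expect_identical(fill_holes(m2), m2)
})

test_that("inter-marker distances behave like Euclidean geometry", {
  m <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 10))
  d <- inter_marker_distances(m)
  expect_equal(unname(d), c(5, 10, sqrt(125)))

  # rigid translation invariance across random translations
  set.seed(31)
  for (i in 1:20) {
    t3 <- runif(3, -50, 50)
    expect_equal(inter_marker_distances(sweep(m, 2, t3, `+`)), d)
  }

  # moving one marker changes exactly two of the three distances
  m2 <- m; m2[2, ] <- m2[2, ] + c(2, 0, 0)
  d2 <- inter_marker_distances(m2)
  expect_identical(sum(abs(d2 - d) > 1e-12), 2L)

  err <- tryCatch(inter_marker_distances(m[1:2, ]),
                  igrt_marker_arity_error = function(e) e)
  expect_identical(err$count, 2L)
})

test_that("marker centroid is the coordinate-wise mean and translates linearly", {
  m <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  expect_equal(unname(marker_centroid(m)), c(2, 2, 0))
  expect_equal(unname(marker_centroid(m[1, , drop = FALSE])), c(0, 0, 0))
  set.seed(41)
  t3 <- rnorm(3)
  expect_equal(marker_centroid(sweep(m, 2, t3, `+`)),
               marker_centroid(m) + t3, ignore_attr = TRUE)
})
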