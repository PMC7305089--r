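test_that("FM-ERB centroid distance is a Euclidean metric", {
  expect_identical(absolute_centroid_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(absolute_centroid_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  a <- c(1.2, -3.4, 5.6); b <- c(-7.1, 0.2, 2.2)
  expect_equal(absolute_centroid_distance(a, b),
               absolute_centroid_distance(b, a))
})

test_that("reference scan selection is an argmin under a hard tolerance", {
  expect_identical(select_reference_cbct(5.0, c(5.4, 5.05, 6.2)), 2L)
  expect_error(select_reference_cbct(5.0, c(6.5, 7.0)),
               class = "igrt_no_reference_error")

  # brute-force argmin oracle over random candidate sets
  set.seed(13)
  for (i in 1:25) {
    d_ct <- runif(1, 0, 6)
    d_cb <- runif(sample(3:30, 1), 0, 8)
    diffs <- abs(d_cb - d_ct)
    if (min(diffs) >= 1.0) {
      expect_error(select_reference_cbct(d_ct, d_cb),
                   class = "igrt_no_reference_error")
    } else {
      ref <- select_reference_cbct(d_ct, d_cb)
      best <- which(diffs == min(diffs))[1]  # enumeration; earliest on ties
      expect_identical(ref, best)
    }
  }
  # tie broken to the earliest fraction
  expect_identical(select_reference_cbct(5.0, c(5.3, 4.7, 9.9)), 1L)
})

test_that("inter- and intrafractional shifts are centroid differences", {
  cen <- rbind(c(0, 0, 0), c(1, 2, 3), c(0, 0, 0), c(-1, 0, 2))
  s <- interfraction_shifts(cen, reference_index = 1)
  expect_equal(s$shifts[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(s$shifts[2, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_identical(s$reference_index, 1L)

  same <- interfraction_shifts(matrix(5, 4, 3), reference_index = 2)
  expect_true(all(same$shifts == 0))

  pre <- list(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  post <- list(sweep(pre[[1]], 2, c(0, -2, 1), `+`))
  intra <- intrafraction_shifts(pre, post)
  expect_equal(intra$shifts[1, ], c(0, -2, 1), ignore_attr = TRUE)
  expect_true(all(intrafraction_shifts(pre, pre)$shifts == 0))
})

test_that("per-patient statistics match hand computation", {
  s <- shift_series(1, "inter", cbind(c(1, 3), c(-1, 1), c(2, 2)))
  st <- per_patient_stats(s, exclude_reference = FALSE)
  expect_equal(unname(st$mean), c(2, 0, 2))
  expect_equal(unname(st$sd), c(sqrt(2), sqrt(2), 0))

  # the reference fraction is excluded by default
  r <- shift_series(1, "inter", rbind(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3)),
                    reference_index = 1)
  str <- per_patient_stats(r)
  expect_equal(unname(str$mean), c(2, 2, 2))
  expect_identical(str$n, 2L)
})

test_that("population statistics decompose into mu, SD, Sigma, sigma", {
  s1 <- shift_series(1, "inter", cbind(c(1, 3), c(1, 3), c(1, 3)))
  s2 <- shift_series(2, "inter", cbind(c(-1, 1), c(-1, 1), c(-1, 1)))
  st <- population_stats(list(s1, s2), exclude_reference = FALSE)
  expect_equal(unname(st$stats["mu", ]), rep(1, 3))
  expect_equal(unname(st$stats["Sigma", ]), rep(sqrt(2), 3))
  expect_equal(unname(st$stats["sigma", ]), rep(sqrt(2), 3))

  const <- lapply(1:3, function(p)
    shift_series(p, "inter", matrix(2.5, 4, 3)))
  stc <- population_stats(const, exclude_reference = FALSE)
  expect_equal(unname(stc$stats["mu", ]), rep(2.5, 3))
  expect_true(all(stc$stats[c("SD", "Sigma", "sigma"), ] == 0))

  expect_error(population_stats(list(s1)), class = "igrt_cohort_size_error")
})

test_that("pooled SD squares to Sigma^2 + sigma^2 on large cohorts", {
  mp <- motion_params(group_mean = c(-0.22, 0.42, -0.03),
                      sigma_systematic = c(1.12, 2.28, 1.48),
                      sigma_random = c(1.89, 3.19, 2.10))
  ser <- sample_motion(mp, 150, 28, seed = 17)
  st <- population_stats(ser, exclude_reference = FALSE)
  lhs <- st$stats["SD", ]^2
  rhs <- st$stats["Sigma", ]^2 + st$stats["sigma", ]^2
  expect_true(all(abs(lhs - rhs) / rhs < 0.10))
})

test_that("adding a constant shifts mu and leaves Sigma, sigma, SD unchanged", {
  mp <- motion_params(sigma_systematic = 1.5, sigma_random = 2.5)
  ser <- sample_motion(mp, 20, 10, seed = 23)
  st0 <- population_stats(ser, exclude_reference = FALSE)
  c3 <- c(4, -2, 7)
  shifted <- lapply(ser, function(s)
    shift_series(s$patient_id, s$kind, sweep(s$shifts, 2, c3, `+`)))
  st1 <- population_stats(shifted, exclude_reference = FALSE)
  expect_equal(st1$stats["mu", ], st0$stats["mu", ] + c3)
  expect_equal(st1$stats[c("SD", "Sigma", "sigma"), ],
               st0$stats[c("SD", "Sigma", "sigma"), ])
})

test_that("generator truth is recovered through the statistics chain", {
  # scaled-down replicate study: random error within 10%, systematic within
  # the sampling-theory prediction sqrt(Sigma^2 + sigma^2/n)
  mp <- motion_params(sigma_systematic = 2.28, sigma_random = 3.19)
  reps <- 40
  est <- vapply(seq_len(reps), function(r) {
    ser <- sample_motion(mp, 31, 28, seed = 100 + r)
    st <- population_stats(ser, exclude_reference = FALSE)
    c(st$stats["Sigma", 2], st$stats["sigma", 2])
  }, numeric(2))
  expect_lt(abs(mean(est[2, ]) - 3.19) / 3.19, 0.05)
  target <- sqrt(2.28^2 + 3.19^2 / 28)
  expect_lt(abs(mean(est[1, ]) - target) / target, 0.10)
})

test_that("measured motion from rendered scans matches the planted truth", {
  cohort <- generate_cohort(n_patients = 2, n_fractions = 5,
                            grid = small_grid(), config = small_config(),
                            inter = motion_params(sigma_systematic = 1.5,
                                                  sigma_random = 2.0),
                            intra = motion_params(sigma_systematic = 0.5,
                                                  sigma_random = 1.0),
                            noise_sd = 20, seed = 77)
  measured <- measure_cohort_motion(cohort)
  expect_length(measured$excluded, 0L)
  for (k in seq_along(measured$inter)) {
    s <- measured$inter[[k]]
    p <- s$patient_id
    truth <- cohort$patients[[p]]$inter_true$shifts
    rel <- sweep(truth, 2, truth[s$reference_index, ], `-`)
    expect_lt(max(abs(s$shifts - rel)), 0.5 * max(small_grid()$spacing))
  }
  # intrafraction series come from exact marker coordinates
  for (k in seq_along(measured$intra)) {
    s <- measured$intra[[k]]
    expect_equal(s$shifts, cohort$patients[[s$patient_id]]$intra_true$shifts,
                 tolerance = 1e-10)
  }
})
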