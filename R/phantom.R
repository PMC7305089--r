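#' Phantom configuration
#'
#' Geometry and intensity parameters of the digital pelvis phantom. The
#' defaults emulate the clinical setting the package targets: an air-filled
#' endorectal balloon (ERB, ~65 cm^3) inside the rectum, a prostate-sized
#' clinical target volume (CTV) anterior to it carrying three implanted
#' fiducial markers (two in the apex region, one near the base), and a
#' planning target volume (PTV) grown from the CTV by a per-axis margin.
#' All lengths are mm in the (LR, SI, AP) patient frame.
#'
#' @param erb_center ERB centre.
#' @param erb_semi_axes ERB ellipsoid semi-axes; the default (23, 33, 20)
#'   gives ~64 cm^3, matching a balloon inflated with ~65 cm^3 of air.
#' @param rectum_clearance_mm added to the ERB semi-axes to form the rectum
#'   ellipsoid (same centre).
#' @param wall_thickness_mm thickness of the anterior rectal wall shell.
#' @param ctv_center,ctv_semi_axes prostate/CTV ellipsoid.
#' @param ptv_margin_mm per-axis CTV-to-PTV expansion. The default
#'   (5, 9, 7) mm covers the van Herk margins this cohort produces.
#' @param marker_offsets 3 x 3 matrix of marker positions relative to the CTV
#'   centre (rows = markers).
#' @param marker_jitter_sd_mm SD of the seeded per-patient jitter applied to
#'   marker positions.
#' @param marker_min_separation_mm required pairwise marker distance.
#' @param marker_radius_mm radius of the rendered marker blob; 3.5 mm spans a
#'   3x3x3 voxel block on the default 2 mm grid.
#' @param intensity_background,intensity_erb,intensity_marker HU-like levels
#'   for soft tissue, balloon air and gold markers.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(erb_center = c(0, 0, -34),
                           erb_semi_axes = c(23, 33, 20),
                           rectum_clearance_mm = c(4, 7, 4),
                           wall_thickness_mm = 4,
                           ctv_center = c(0, 2, 2),
                           ctv_semi_axes = c(20, 18, 12),
                           ptv_margin_mm = c(5, 9, 7),
                           marker_offsets = rbind(c(-8, -10, 0),
                                                  c(8, -10, 2),
                                                  c(0, 12, -2)),
                           marker_jitter_sd_mm = 1,
                           marker_min_separation_mm = 10,
                           marker_radius_mm = 3.5,
                           intensity_background = 30,
                           intensity_erb = -980,
                           intensity_marker = 3000) {
  cfg <- list(erb_center = as.numeric(erb_center),
              erb_semi_axes = as.numeric(erb_semi_axes),
              rectum_clearance_mm = rep_len(as.numeric(rectum_clearance_mm), 3L),
              wall_thickness_mm = as.numeric(wall_thickness_mm),
              ctv_center = as.numeric(ctv_center),
              ctv_semi_axes = as.numeric(ctv_semi_axes),
              ptv_margin_mm = rep_len(as.numeric(ptv_margin_mm), 3L),
              marker_offsets = as_shift_matrix(marker_offsets),
              marker_jitter_sd_mm = as.numeric(marker_jitter_sd_mm),
              marker_min_separation_mm = as.numeric(marker_min_separation_mm),
              marker_radius_mm = as.numeric(marker_radius_mm),
              intensity_background = as.numeric(intensity_background),
              intensity_erb = as.numeric(intensity_erb),
              intensity_marker = as.numeric(intensity_marker))
  if (any(cfg$erb_semi_axes <= 0) || any(cfg$ctv_semi_axes <= 0))
    stop("ellipsoid semi-axes must be positive")
  if (nrow(cfg$marker_offsets) != 3L)
    stop("exactly 3 marker positions are required")
  class(cfg) <- "phantom_config"
  cfg
}

# logical ellipsoid mask: voxel centres with sum(((x-c)/a)^2) <= 1
ellipsoid_mask <- function(grid, center, semi_axes) {
  u <- ((axis_coords(grid, 1L) - center[1]) / semi_axes[1])^2
  v <- ((axis_coords(grid, 2L) - center[2]) / semi_axes[2])^2
  w <- ((axis_coords(grid, 3L) - center[3]) / semi_axes[3])^2
  outer(outer(u, v, `+`), w, `+`) <= 1
}

check_bounds <- function(grid, center, semi_axes, what) {
  ext <- grid_extent(grid)
  lo <- center - semi_axes
  hi <- center + semi_axes
  if (any(lo < ext["min", ] - 1e-9) || any(hi > ext["max", ] + 1e-9))
    stop(errorCondition(
      sprintf("structure '%s' exceeds the grid bounds", what),
      class = c("igrt_bounds_error", "error", "condition"), structure = what))
  invisible(TRUE)
}

#' Generate one patient's phantom geometry
#'
#' Builds the analytic shapes and the voxelised structure masks (CTV, PTV,
#' rectum, anterior_rectal_wall, ERB) for one patient. Marker positions are
#' the configured offsets around the CTV centre plus a seeded Gaussian jitter,
#' so each patient carries a slightly different implant pattern.
#'
#' @param grid a [grid_spec].
#' @param config a [phantom_config].
#' @param seed integer seed for the marker jitter.
#' @return list of class `phantom_geometry`: grid, analytic shape parameters,
#'   `marker_positions` (3 x 3 mm matrix), `structure_masks` (named list of
#'   logical arrays) and the intensity levels.
#' @export
generate_geometry <- function(grid, config = phantom_config(), seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(config, "phantom_config"))
  rectum_semi <- config$erb_semi_axes + config$rectum_clearance_mm
  ptv_semi <- config$ctv_semi_axes + config$ptv_margin_mm
  check_bounds(grid, config$erb_center, config$erb_semi_axes, "ERB")
  check_bounds(grid, config$erb_center, rectum_semi, "rectum")
  check_bounds(grid, config$ctv_center, config$ctv_semi_axes, "CTV")
  check_bounds(grid, config$ctv_center, ptv_semi, "PTV")

  set.seed(as.integer(seed))
  jitter <- matrix(stats::rnorm(9L, 0, config$marker_jitter_sd_mm), 3L, 3L)
  markers <- sweep(config$marker_offsets + jitter, 2L, config$ctv_center, `+`)
  dmat <- as.matrix(stats::dist(markers))
  if (min(dmat[upper.tri(dmat)]) < config$marker_min_separation_mm)
    stop(errorCondition(
      "marker positions violate the minimum pairwise separation",
      class = c("igrt_geometry_error", "error", "condition")))
  for (i in 1:3)
    check_bounds(grid, markers[i, ], rep(config$marker_radius_mm, 3L),
                 sprintf("marker_%d", i))

  erb <- ellipsoid_mask(grid, config$erb_center, config$erb_semi_axes)
  rectum <- ellipsoid_mask(grid, config$erb_center, rectum_semi)
  inner <- ellipsoid_mask(grid, config$erb_center,
                          rectum_semi - config$wall_thickness_mm)
  ap <- axis_coords(grid, 3L)
  anterior <- array(rep(ap >= config$erb_center[3], each = prod(grid$shape[1:2])),
                    grid$shape)
  wall <- rectum & !inner & anterior
  ctv <- ellipsoid_mask(grid, config$ctv_center, config$ctv_semi_axes)
  ptv <- ellipsoid_mask(grid, config$ctv_center, ptv_semi)
  if (any(erb & !rectum)) stop("internal error: ERB not contained in rectum")

  structure(list(grid = grid, config = config,
                 erb_center = config$erb_center,
                 erb_semi_axes = config$erb_semi_axes,
                 rectum_semi_axes = rectum_semi,
                 ctv_center = config$ctv_center,
                 ctv_semi_axes = config$ctv_semi_axes,
                 ptv_semi_axes = ptv_semi,
                 marker_positions = as_shift_matrix(markers),
                 structure_masks = list(CTV = ctv, PTV = ptv, rectum = rectum,
                                        anterior_rectal_wall = wall, ERB = erb),
                 intensities = c(background = config$intensity_background,
                                 erb = config$intensity_erb,
                                 marker = config$intensity_marker)),
            class = "phantom_geometry")
}

#' Motion model parameters for one error component
#'
#' Per-axis Gaussian motion model: patient p draws a systematic offset
#' m_p ~ N(group_mean, sigma_systematic^2) once, and fraction f adds an
#' independent random term e_pf ~ N(0, sigma_random^2); axes are independent.
#'
#' @param group_mean per-axis mean offset (mm), the generative mu.
#' @param sigma_systematic per-axis SD of the patient offsets (mm), the
#'   generative Sigma.
#' @param sigma_random per-axis SD of the per-fraction term (mm), the
#'   generative sigma.
#' @return list of class `motion_params`.
#' @export
motion_params <- function(group_mean = c(0, 0, 0),
                          sigma_systematic = c(0, 0, 0),
                          sigma_random = c(0, 0, 0)) {
  p <- list(group_mean = rep_len(as.numeric(group_mean), 3L),
            sigma_systematic = rep_len(as.numeric(sigma_systematic), 3L),
            sigma_random = rep_len(as.numeric(sigma_random), 3L))
  if (any(!is.finite(unlist(p))))
    stop("motion parameters must be finite")
  if (any(p$sigma_systematic < 0) || any(p$sigma_random < 0))
    stop("motion SDs must be non-negative")
  class(p) <- "motion_params"
  p
}

#' Reported interfraction motion parameters
#'
#' Default generative parameters for the interfractional (setup) and
#' intrafractional (target drift) components: group mean, systematic and
#' random SDs per axis as observed in a 31-patient ERB/FM cohort.
#' @return a [motion_params] object.
#' @export
reported_inter_params <- function() {
  motion_params(group_mean = c(-0.22, 0.42, -0.03),
                sigma_systematic = c(1.12, 2.28, 1.48),
                sigma_random = c(1.89, 3.19, 2.10))
}

#' @rdname reported_inter_params
#' @export
reported_intra_params <- function() {
  motion_params(group_mean = c(0.04, -0.28, -0.70),
                sigma_systematic = c(0.44, 0.69, 0.80),
                sigma_random = c(1.91, 2.30, 2.27))
}

#' Sample true per-fraction shifts for a cohort
#'
#' Draws, for each patient, a systematic offset and per-fraction random
#' offsets under the Gaussian motion model and records the resulting true
#' shift of every fraction relative to the planning scan.
#'
#' @param motion a [motion_params].
#' @param n_patients,n_fractions cohort dimensions (>= 1).
#' @param seed integer seed.
#' @param kind label stored on each series: "inter" or "intra".
#' @return list of [shift_series] objects, one per patient, each with an
#'   attribute-free extra field `systematic_mm` holding the patient's true
#'   systematic offset.
#' @export
sample_motion <- function(motion, n_patients, n_fractions, seed = 1L,
                          kind = c("inter", "intra")) {
  stopifnot(inherits(motion, "motion_params"),
            n_patients >= 1L, n_fractions >= 1L)
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  lapply(seq_len(n_patients), function(p) {
    m_p <- motion$group_mean +
      stats::rnorm(3L, 0, motion$sigma_systematic)
    e <- matrix(stats::rnorm(3L * n_fractions, 0,
                             rep(motion$sigma_random, each = n_fractions)),
                n_fractions, 3L)
    s <- shift_series(patient_id = p, kind = kind,
                      shifts = sweep(e, 2L, m_p, `+`))
    s$systematic_mm <- m_p
    s
  })
}

marker_blob_mask <- function(grid, center, radius) {
  u <- (axis_coords(grid, 1L) - center[1])^2
  v <- (axis_coords(grid, 2L) - center[2])^2
  w <- (axis_coords(grid, 3L) - center[3])^2
  outer(outer(u, v, `+`), w, `+`) <= radius^2
}

#' Render a CT/CBCT-like volume of the phantom
#'
#' The ERB and the fiducial markers are translated by `shift` analytically
#' (shape centres move before voxelisation, so ground-truth centroids are
#' exact up to voxelisation); the soft-tissue background stays fixed.
#' Optional additive Gaussian noise emulates image noise.
#'
#' @param geometry a [phantom_geometry].
#' @param shift mm triple (LR, SI, AP) applied to ERB and markers.
#' @param noise_sd SD of additive Gaussian noise (intensity units, >= 0).
#' @param seed seed for the noise draw.
#' @param grid target [grid_spec]; defaults to the geometry's grid.
#' @return an [image_volume].
#' @export
render_volume <- function(geometry, shift = c(0, 0, 0), noise_sd = 0,
                          seed = 1L, grid = geometry$grid) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  shift <- rep_len(as.numeric(shift), 3L)
  if (any(!is.finite(shift))) stop("`shift` must be finite")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  cfg <- geometry$config
  if (cfg$intensity_marker <= cfg$intensity_background)
    stop(errorCondition(
      "marker intensity does not exceed the background; markers would be unsegmentable",
      class = c("igrt_render_error", "error", "condition")))
  erb_c <- geometry$erb_center + shift
  check_bounds(grid, erb_c, geometry$erb_semi_axes, "ERB")
  markers <- sweep(geometry$marker_positions, 2L, shift, `+`)
  for (i in 1:3)
    check_bounds(grid, markers[i, ], rep(cfg$marker_radius_mm, 3L),
                 sprintf("marker_%d", i))
  vox <- array(cfg$intensity_background, grid$shape)
  vox[ellipsoid_mask(grid, erb_c, geometry$erb_semi_axes)] <- cfg$intensity_erb
  for (i in 1:3)
    vox[marker_blob_mask(grid, markers[i, ], cfg$marker_radius_mm)] <-
      cfg$intensity_marker
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vox <- vox + stats::rnorm(length(vox), 0, noise_sd)
  }
  image_volume(vox, grid)
}

#' Generate a synthetic static dose grid
#'
#' A smooth IMRT-like dose field: the prescription dose everywhere inside the
#' PTV ellipsoid, with a Gaussian-shoulder falloff outside parameterised by
#' the distance at which dose drops to 50%.
#'
#' @param geometry a [phantom_geometry].
#' @param prescription_gy total prescribed dose (default 50.4 Gy).
#' @param n_fractions,dose_per_fraction_gy fractionation scheme
#'   (28 x 1.8 Gy by default).
#' @param d50_mm distance outside the PTV surface at which dose reaches 50%
#'   of prescription.
#' @param grid target [grid_spec].
#' @return a [dose_grid].
#' @export
generate_dose_grid <- function(geometry, prescription_gy = 50.4,
                               n_fractions = 28L, dose_per_fraction_gy = 1.8,
                               d50_mm = 10, grid = geometry$grid) {
  stopifnot(inherits(geometry, "phantom_geometry"), prescription_gy > 0,
            d50_mm > 0)
  semi <- geometry$ptv_semi_axes
  cen <- geometry$ctv_center
  u <- ((axis_coords(grid, 1L) - cen[1]) / semi[1])^2
  v <- ((axis_coords(grid, 2L) - cen[2]) / semi[2])^2
  w <- ((axis_coords(grid, 3L) - cen[3]) / semi[3])^2
  r <- sqrt(outer(outer(u, v, `+`), w, `+`))
  d_mm <- pmax(r - 1, 0) * min(semi)   # lower bound on mm distance to the PTV
  dose <- prescription_gy * 0.5^((d_mm / d50_mm)^2)
  dose_grid(image_volume(dose, grid), n_fractions = n_fractions,
            dose_per_fraction_gy = dose_per_fraction_gy,
            prescription_gy = prescription_gy)
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Produces per-patient geometry (seeded marker jitter), true inter- and
#' intrafractional shift series, pre/post-treatment marker positions for
#' every fraction, and a shared static dose grid. Image volumes are *not*
#' materialised here (a 31 x 28 cohort would not fit in memory); they are
#' rendered on demand with [cohort_volume()].
#'
#' @param n_patients,n_fractions cohort dimensions; defaults 31 patients with
#'   28 fractions each, the size of the clinical cohort emulated.
#' @param grid a [grid_spec]; default 96 x 96 x 64 voxels at 2 mm.
#' @param config a [phantom_config].
#' @param inter,intra [motion_params] for the two error components; defaults
#'   are the reported cohort values ([reported_inter_params()]).
#' @param noise_sd image noise SD used when volumes are rendered.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @return list of class `cohort_dataset` with elements `patients` (each:
#'   geometry, inter/intra [shift_series], pre/post marker positions per
#'   fraction), `dose`, `grid`, `config`, `counts` and `seed`.
#' @export
generate_cohort <- function(n_patients = 31L, n_fractions = 28L,
                            grid = grid_spec(c(96L, 96L, 64L), 2),
                            config = phantom_config(),
                            inter = reported_inter_params(),
                            intra = reported_intra_params(),
                            noise_sd = 20, seed = 1L) {
  seed <- as.integer(seed)
  inter_true <- sample_motion(inter, n_patients, n_fractions,
                              seed = derive_seed(seed, "inter"), kind = "inter")
  intra_true <- sample_motion(intra, n_patients, n_fractions,
                              seed = derive_seed(seed, "intra"), kind = "intra")
  patients <- lapply(seq_len(n_patients), function(p) {
    geom <- generate_geometry(grid, config,
                              seed = derive_seed(seed, paste0("geom", p)))
    pre <- lapply(seq_len(n_fractions), function(f)
      sweep(geom$marker_positions, 2L, inter_true[[p]]$shifts[f, ], `+`))
    post <- lapply(seq_len(n_fractions), function(f)
      sweep(pre[[f]], 2L, intra_true[[p]]$shifts[f, ], `+`))
    list(patient_id = p, geometry = geom,
         inter_true = inter_true[[p]], intra_true = intra_true[[p]],
         markers_pre = pre, markers_post = post)
  })
  dose <- generate_dose_grid(patients[[1L]]$geometry,
                             prescription_gy = 50.4,
                             n_fractions = n_fractions,
                             dose_per_fraction_gy = 50.4 / n_fractions,
                             grid = grid)
  structure(list(patients = patients, dose = dose, grid = grid,
                 config = config, noise_sd = noise_sd, seed = seed,
                 n_patients = as.integer(n_patients),
                 n_fractions = as.integer(n_fractions),
                 counts = cohort_counts(n_patients, n_fractions)),
            class = "cohort_dataset")
}

cohort_counts <- function(n_patients, n_fractions) {
  n_patients <- as.integer(n_patients); n_fractions <- as.integer(n_fractions)
  list(n_planning_ct = n_patients,
       n_cbct = n_patients * n_fractions,
       n_intrafraction_records = 2L * n_patients * n_fractions)
}

#' Render one volume of a cohort on demand
#'
#' @param cohort a `cohort_dataset`.
#' @param patient patient index.
#' @param fraction fraction index, or 0 for the planning scan (zero shift).
#' @return an [image_volume].
#' @export
cohort_volume <- function(cohort, patient, fraction) {
  pt <- cohort$patients[[patient]]
  shift <- if (fraction == 0L) c(0, 0, 0) else pt$inter_true$shifts[fraction, ]
  render_volume(pt$geometry, shift = shift, noise_sd = cohort$noise_sd,
                seed = derive_seed(cohort$seed,
                                   sprintf("render%d_%d", patient, fraction)))
}

# Deterministic per-stage seed derivation (kept below 2^31).
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) *
             seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483629)
}
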