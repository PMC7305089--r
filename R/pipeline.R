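#' Pipeline configuration
#'
#' Single configuration object for an end-to-end run: phantom grid and
#' geometry, motion parameters, segmentation thresholds, reference-scan
#' tolerance, DVH resolution, adaptation rule and seed. Defaults reproduce
#' the documented example run on a small cohort.
#'
#' @param n_patients,n_fractions cohort dimensions.
#' @param grid a [grid_spec].
#' @param phantom a [phantom_config].
#' @param inter,intra [motion_params] for the two motion components.
#' @param noise_sd image noise SD (intensity units).
#' @param high_threshold,low_threshold segmentation thresholds; `NULL` means
#'   per-volume defaults ([default_thresholds()]).
#' @param reference_tolerance_mm tolerance for reference-scan selection.
#' @param dvh_bin_width_gy,dvh_max_dose_gy DVH grid.
#' @param intra_weight weight of the intrafraction displacement in the
#'   composed per-fraction shift ([compose_shifts()]).
#' @param adapt_threshold,adapt_min_violations adaptation-rule parameters.
#' @param alpha significance level of the DVH comparison.
#' @param seed top-level seed; all stage seeds derive from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 5L, n_fractions = 10L,
                            grid = grid_spec(c(96L, 96L, 64L), 2),
                            phantom = phantom_config(),
                            inter = reported_inter_params(),
                            intra = reported_intra_params(),
                            noise_sd = 20,
                            high_threshold = NULL, low_threshold = NULL,
                            reference_tolerance_mm = 1.0,
                            dvh_bin_width_gy = 0.5, dvh_max_dose_gy = 59.5,
                            intra_weight = 0.5,
                            adapt_threshold = 0.9, adapt_min_violations = 2L,
                            alpha = 0.05, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_fractions = as.integer(n_fractions),
              grid = grid, phantom = phantom, inter = inter, intra = intra,
              noise_sd = as.numeric(noise_sd),
              high_threshold = high_threshold, low_threshold = low_threshold,
              reference_tolerance_mm = as.numeric(reference_tolerance_mm),
              dvh_bin_width_gy = as.numeric(dvh_bin_width_gy),
              dvh_max_dose_gy = as.numeric(dvh_max_dose_gy),
              intra_weight = as.numeric(intra_weight),
              adapt_threshold = as.numeric(adapt_threshold),
              adapt_min_violations = as.integer(adapt_min_violations),
              alpha = as.numeric(alpha), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration (fail fast)
#'
#' Rejects any configuration the pipeline would later fail on: wrong types,
#' non-positive sizes, out-of-range probabilities, geometry that does not
#' fit the grid.
#'
#' @param config a `pipeline_config`.
#' @return `config`, invisibly; errors on the first violation.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  with(config, {
    if (!inherits(grid, "grid_spec")) stop("grid must be a grid_spec")
    if (!inherits(phantom, "phantom_config"))
      stop("phantom must be a phantom_config")
    if (!inherits(inter, "motion_params") || !inherits(intra, "motion_params"))
      stop("inter/intra must be motion_params")
    if (is.na(n_patients) || n_patients < 1L) stop("n_patients must be >= 1")
    if (is.na(n_fractions) || n_fractions < 1L) stop("n_fractions must be >= 1")
    if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
    if (!is.finite(reference_tolerance_mm) || reference_tolerance_mm <= 0)
      stop("reference_tolerance_mm must be > 0")
    if (!is.finite(dvh_bin_width_gy) || dvh_bin_width_gy <= 0)
      stop("dvh_bin_width_gy must be > 0")
    if (!is.finite(dvh_max_dose_gy) || dvh_max_dose_gy <= 0)
      stop("dvh_max_dose_gy must be > 0")
    if (!is.finite(intra_weight) || intra_weight < 0 || intra_weight > 1)
      stop("intra_weight must lie in [0, 1]")
    if (!is.finite(adapt_threshold) || adapt_threshold < 0 ||
        adapt_threshold > 1)
      stop("adapt_threshold must lie in [0, 1]")
    if (is.na(adapt_min_violations) || adapt_min_violations < 1L ||
        adapt_min_violations > 4L)
      stop("adapt_min_violations must lie in 1..4")
    if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
      stop("alpha must lie in (0, 1)")
    if (is.na(seed)) stop("seed must be an integer")
  })
  # geometry must fit the grid (raises igrt_bounds_error otherwise)
  generate_geometry(config$grid, config$phantom, seed = config$seed)
  invisible(config)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> render/segment -> reference selection -> shift
#' extraction -> error statistics -> margins -> motion-perturbed DVH ->
#' adaptation check, and (optionally) writes all artifacts plus a
#' provenance record to `output_dir`.
#'
#' @param config a [pipeline_config].
#' @param output_dir directory for artifacts, or `NULL` to skip writing.
#' @return list of class `pipeline_report`: `cohort` counts, `inter_stats`,
#'   `intra_stats`, `margins`, `dvh` (static/motion curves and signed-rank
#'   test), `adapt` (per-patient decisions), `excluded`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  validate_config(config)
  cohort <- generate_cohort(config$n_patients, config$n_fractions,
                            grid = config$grid, config = config$phantom,
                            inter = config$inter, intra = config$intra,
                            noise_sd = config$noise_sd, seed = config$seed)
  measured <- measure_cohort_motion(
    cohort, reference_tolerance_mm = config$reference_tolerance_mm)
  inter_stats <- population_stats(measured$inter, exclude_reference = TRUE)
  intra_stats <- population_stats(measured$intra, exclude_reference = FALSE)
  margins <- margin_report(inter_stats, intra_stats)

  geom <- cohort$patients[[1L]]$geometry
  shifts_list <- lapply(seq_along(cohort$patients), function(p) {
    compose_shifts(cohort$patients[[p]]$inter_true,
                   cohort$patients[[p]]$intra_true,
                   intra_weight = config$intra_weight)
  })
  dvh <- motion_dose_impact(cohort$dose, geom$structure_masks$CTV,
                            shifts_list, alpha = config$alpha)
  adapt <- cohort_adapt_check(cohort,
                              n_inspect = min(4L, config$n_fractions),
                              threshold = config$adapt_threshold,
                              min_violations = config$adapt_min_violations)

  report <- structure(
    list(counts = cohort$counts, inter_stats = inter_stats,
         intra_stats = intra_stats, margins = margins, dvh = dvh,
         adapt = adapt, excluded = measured$excluded,
         provenance = list(seed = config$seed,
                           n_patients = config$n_patients,
                           n_fractions = config$n_fractions,
                           r_version = as.character(getRversion()),
                           package_version =
                             as.character(utils::packageVersion("igrtmotion")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pipeline_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(output_dir, ...)
    write_shift_table(measured$inter, fp("shifts_inter.csv"))
    write_shift_table(measured$intra, fp("shifts_intra.csv"))
    write_error_stats(inter_stats, fp("error_stats_inter.csv"),
                      fp("error_stats_inter.json"))
    write_error_stats(intra_stats, fp("error_stats_intra.csv"),
                      fp("error_stats_intra.json"))
    write_margin_table(margins, fp("margins.csv"), fp("margins.json"))
    write_dvh(dvh$dvh_static, fp("dvh_static.csv"))
    write_dvh(dvh$dvh_motion, fp("dvh_motion.csv"))
    jsonlite::write_json(dvh$test, fp("dvh_test.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(adapt, fp("adapt_decisions.csv"), row.names = FALSE)
    cfg_json <- fp("config.json")
    jsonlite::write_json(config_summary(config), cfg_json,
                         auto_unbox = TRUE, digits = NA)
    prov <- report$provenance
    prov$config_md5 <- unname(tools::md5sum(cfg_json))
    jsonlite::write_json(prov, fp("provenance.json"), auto_unbox = TRUE,
                         digits = NA)
    report$provenance <- prov
  }
  report
}

# flat, JSON-friendly view of a configuration (for provenance)
config_summary <- function(config) {
  list(n_patients = config$n_patients, n_fractions = config$n_fractions,
       grid_shape = config$grid$shape, grid_spacing = config$grid$spacing,
       grid_origin = config$grid$origin,
       noise_sd = config$noise_sd,
       reference_tolerance_mm = config$reference_tolerance_mm,
       dvh_bin_width_gy = config$dvh_bin_width_gy,
       dvh_max_dose_gy = config$dvh_max_dose_gy,
       intra_weight = config$intra_weight,
       adapt_threshold = config$adapt_threshold,
       adapt_min_violations = config$adapt_min_violations,
       alpha = config$alpha, seed = config$seed,
       inter = unclass(config$inter), intra = unclass(config$intra),
       phantom = lapply(unclass(config$phantom), function(x)
         if (is.matrix(x)) as.data.frame(x) else x))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d patients x %d fractions (%d CBCTs)\n",
              x$provenance$n_patients, x$provenance$n_fractions,
              x$counts$n_cbct))
  cat("\nInterfractional error statistics (mm):\n")
  print(round(x$inter_stats$stats, 2))
  cat("\nIntrafractional error statistics (mm):\n")
  print(round(x$intra_stats$stats, 2))
  cat("\nCTV-to-PTV margins (mm):\n")
  print(format_margin_block(x$margins))
  cat(sprintf("\nDVH comparison (motion vs static): p = %.3f (%s)\n",
              x$dvh$test$p_value, x$dvh$test$method))
  cat(sprintf("Adaptation decisions: %d adapt / %d keep\n",
              sum(x$adapt$decision == "adapt"),
              sum(x$adapt$decision == "keep")))
  invisible(x)
}
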