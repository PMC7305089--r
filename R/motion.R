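#' Per-patient shift series
#'
#' Ordered per-fraction displacements (mm) of one patient along LR, SI, AP.
#' For an interfractional series derived from images, shifts are relative to
#' the reference scan (`reference_index`), whose own shift is (0, 0, 0); for
#' generator truth they are relative to the planning geometry and
#' `reference_index` is `NA`.
#'
#' @param patient_id identifier.
#' @param kind "inter" or "intra".
#' @param shifts n_fractions x 3 numeric matrix (mm).
#' @param reference_index index of the reference fraction, or `NA`.
#' @return object of class `shift_series`.
#' @export
shift_series <- function(patient_id, kind = c("inter", "intra"), shifts,
                         reference_index = NA_integer_) {
  kind <- match.arg(kind)
  shifts <- as_shift_matrix(shifts)
  if (anyNA(shifts) || any(!is.finite(shifts)))
    stop("shifts must be finite")
  if (!is.na(reference_index)) {
    if (reference_index < 1L || reference_index > nrow(shifts))
      stop("`reference_index` out of range")
    if (kind == "inter" && any(shifts[reference_index, ] != 0))
      stop("the reference fraction of an inter series must have zero shift")
  }
  structure(list(patient_id = patient_id, kind = kind, shifts = shifts,
                 reference_index = as.integer(reference_index)),
            class = "shift_series")
}

#' @export
print.shift_series <- function(x, ...) {
  cat(sprintf("shift_series (%s) patient %s: %d fractions%s\n", x$kind,
              x$patient_id, nrow(x$shifts),
              if (is.na(x$reference_index)) ""
              else sprintf(", reference fraction %d", x$reference_index)))
  invisible(x)
}

#' Absolute distance between FM and ERB centroids
#'
#' The scalar internal-consistency measure of one image set: the Euclidean
#' distance between the fiducial-marker centroid and the ERB centroid.
#'
#' @param fm_centroid,erb_centroid mm triples.
#' @return distance in mm (>= 0).
#' @export
absolute_centroid_distance <- function(fm_centroid, erb_centroid) {
  a <- as.numeric(fm_centroid); b <- as.numeric(erb_centroid)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("centroids must be finite")
  sqrt(sum((a - b)^2))
}

#' Select the reference CBCT of a patient
#'
#' The reference scan is the fraction whose FM-ERB centroid distance is
#' closest to that of the planning CT, provided the discrepancy is below
#' `tolerance_mm` (default 1 mm); ties break to the earliest fraction.
#'
#' @param delta_ct FM-ERB distance on the planning CT (mm).
#' @param delta_cbcts per-fraction FM-ERB distances (mm).
#' @param tolerance_mm largest acceptable |delta_cbct - delta_ct|.
#' @return index of the reference fraction. If no candidate is within
#'   tolerance, a condition of class `igrt_no_reference_error` is raised (the
#'   patient is excluded from interfraction analysis).
#' @export
select_reference_cbct <- function(delta_ct, delta_cbcts, tolerance_mm = 1.0) {
  stopifnot(length(delta_cbcts) >= 1L, is.finite(delta_ct))
  diffs <- abs(delta_cbcts - delta_ct)
  i <- which.min(diffs)                      # which.min ties -> earliest
  if (diffs[i] >= tolerance_mm)
    stop(errorCondition(
      sprintf("no CBCT within %.2f mm of the planning-CT centroid distance (best %.2f mm)",
              tolerance_mm, diffs[i]),
      class = c("igrt_no_reference_error", "error", "condition"),
      best_mm = diffs[i]))
  i
}

#' Interfractional shifts relative to the reference scan
#'
#' @param erb_centroids n_fractions x 3 matrix of per-fraction ERB centroids
#'   (mm).
#' @param reference_index reference fraction.
#' @param patient_id identifier stored on the series.
#' @return a [shift_series] of kind "inter"; the reference fraction's shift
#'   is exactly (0, 0, 0).
#' @export
interfraction_shifts <- function(erb_centroids, reference_index,
                                 patient_id = NA) {
  cen <- as_shift_matrix(erb_centroids)
  stopifnot(reference_index >= 1L, reference_index <= nrow(cen))
  shifts <- sweep(cen, 2L, cen[reference_index, ], `-`)
  shifts[reference_index, ] <- 0
  shift_series(patient_id, "inter", shifts, reference_index)
}

#' Intrafractional shifts from pre/post-treatment marker positions
#'
#' @param pre_markers,post_markers lists (one element per fraction) of
#'   [marker_set] objects or n x 3 position matrices.
#' @param patient_id identifier stored on the series.
#' @return a [shift_series] of kind "intra": per fraction, the displacement
#'   of the marker centroid from the pre- to the post-treatment image.
#' @export
intrafraction_shifts <- function(pre_markers, post_markers, patient_id = NA) {
  if (length(pre_markers) != length(post_markers))
    stop("pre and post marker lists must have the same length")
  shifts <- t(vapply(seq_along(pre_markers), function(f)
    marker_centroid(post_markers[[f]]) - marker_centroid(pre_markers[[f]]),
    numeric(3L)))
  shift_series(patient_id, "intra", shifts)
}

#' Per-patient mean and SD of a shift series
#'
#' @param series a [shift_series].
#' @param exclude_reference drop the reference fraction before computing the
#'   statistics (default `TRUE`: the reference scan carries a zero shift by
#'   construction and is not an observation).
#' @return list with `mean` and `sd` (per-axis, mm; SD uses the n-1
#'   denominator) and `n` (fractions used).
#' @export
per_patient_stats <- function(series, exclude_reference = TRUE) {
  stopifnot(inherits(series, "shift_series"))
  s <- series$shifts
  if (exclude_reference && !is.na(series$reference_index))
    s <- s[-series$reference_index, , drop = FALSE]
  if (nrow(s) < 2L) stop("at least 2 usable fractions are required for a SD")
  list(mean = stats::setNames(colMeans(s), axis_names()),
       sd = stats::setNames(apply(s, 2L, stats::sd), axis_names()),
       n = nrow(s))
}

#' Cohort error statistics (mu, SD, Sigma, sigma)
#'
#' Decomposes cohort motion into the group systematic deviation mu (mean
#' over patients of the per-patient means), the systematic error Sigma
#' (SD over patients of the per-patient means), the random error sigma
#' (root mean square over patients of the per-patient SDs), and the overall
#' SD (pooled SD of all individual shifts).
#'
#' @param series_list list of [shift_series], one per patient (>= 2).
#' @param exclude_reference passed to [per_patient_stats()].
#' @return object of class `error_stats`: a 4 x 3 matrix `stats` with rows
#'   mu, SD, Sigma, sigma and columns LR, SI, AP, plus `n_patients` and
#'   `n_fractions` (fractions used per patient).
#' @export
population_stats <- function(series_list, exclude_reference = TRUE) {
  if (length(series_list) < 2L)
    stop(errorCondition(
      "the systematic error Sigma is undefined for fewer than 2 patients",
      class = c("igrt_cohort_size_error", "error", "condition")))
  pp <- lapply(series_list, per_patient_stats,
               exclude_reference = exclude_reference)
  means <- t(vapply(pp, `[[`, numeric(3L), "mean"))
  sds <- t(vapply(pp, `[[`, numeric(3L), "sd"))
  pooled <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]$shifts
    if (exclude_reference && !is.na(series_list[[i]]$reference_index))
      s <- s[-series_list[[i]]$reference_index, , drop = FALSE]
    s
  }))
  m <- rbind(mu = colMeans(means),
             SD = apply(pooled, 2L, stats::sd),
             Sigma = apply(means, 2L, stats::sd),
             sigma = sqrt(colMeans(sds^2)))
  colnames(m) <- axis_names()
  structure(list(stats = m, n_patients = length(series_list),
                 n_fractions = pp[[1L]]$n),
            class = "error_stats")
}

#' Construct error statistics directly from known components
#'
#' Convenience constructor used to feed published mu/SD/Sigma/sigma tables
#' into the margin and plan-comparison machinery.
#'
#' @param sigma_sys,sigma_rand per-axis Sigma and sigma (mm).
#' @param mu,sd per-axis group mean and overall SD (mm), optional.
#' @param n_patients,n_fractions provenance, optional.
#' @return an `error_stats` object.
#' @export
error_stats <- function(sigma_sys, sigma_rand, mu = c(0, 0, 0),
                        sd = NA_real_, n_patients = NA_integer_,
                        n_fractions = NA_integer_) {
  m <- rbind(mu = rep_len(as.numeric(mu), 3L),
             SD = rep_len(as.numeric(sd), 3L),
             Sigma = rep_len(as.numeric(sigma_sys), 3L),
             sigma = rep_len(as.numeric(sigma_rand), 3L))
  if (any(m[c("Sigma", "sigma"), ] < 0, na.rm = TRUE))
    stop("Sigma and sigma must be >= 0")
  colnames(m) <- axis_names()
  structure(list(stats = m, n_patients = n_patients,
                 n_fractions = n_fractions), class = "error_stats")
}

#' @export
print.error_stats <- function(x, digits = 2, ...) {
  cat(sprintf("error_stats (%s patients, %s fractions):\n",
              x$n_patients, x$n_fractions))
  print(round(x$stats, digits))
  invisible(x)
}

#' Compose inter- and intrafractional shifts per fraction
#'
#' The effective per-fraction displacement applied to the dose sampling
#' point: the interfractional setup residual plus a weighted intrafraction
#' displacement. The default weight 0.5 is the time-averaged position under
#' a linear drift from the pre- to the post-treatment position.
#'
#' @param inter,intra [shift_series] (or n x 3 matrices) with equal fraction
#'   counts.
#' @param intra_weight weight on the intrafraction displacement.
#' @return n x 3 matrix of composed shifts (mm).
#' @export
compose_shifts <- function(inter, intra, intra_weight = 0.5) {
  a <- if (inherits(inter, "shift_series")) inter$shifts else as_shift_matrix(inter)
  b <- if (inherits(intra, "shift_series")) intra$shifts else as_shift_matrix(intra)
  if (nrow(a) != nrow(b)) stop("fraction counts differ")
  a + intra_weight * b
}

#' Segment a cohort and extract measured motion
#'
#' Runs the image-analysis arm of the pipeline on a synthetic cohort: for
#' each patient, segments ERB and markers on the planning render and every
#' fraction render, selects the reference scan from FM-ERB centroid
#' distances, and returns measured interfractional shift series (relative to
#' the reference) plus intrafractional series from the recorded pre/post
#' marker positions. Patients without an admissible reference scan are
#' reported and dropped from the interfraction list.
#'
#' @param cohort a `cohort_dataset`.
#' @param patients subset of patient indices (default all).
#' @param reference_tolerance_mm tolerance for [select_reference_cbct()].
#' @return list with `inter` and `intra` (lists of [shift_series]),
#'   `erb_centroids`, `reference_index` per patient, and `excluded`
#'   (patient ids without reference).
#' @export
measure_cohort_motion <- function(cohort, patients = NULL,
                                  reference_tolerance_mm = 1.0) {
  if (is.null(patients)) patients <- seq_along(cohort$patients)
  inter <- list(); intra <- list(); excluded <- integer(0)
  cents <- list(); refs <- integer(0)
  for (p in patients) {
    pt <- cohort$patients[[p]]
    nf <- cohort$n_fractions
    plan <- cohort_volume(cohort, p, 0L)
    d_ct <- absolute_centroid_distance(
      marker_centroid(segment_markers(plan)),
      segment_erb(plan)$centroid_mm)
    erb_cen <- matrix(NA_real_, nf, 3L)
    d_cbct <- numeric(nf)
    for (f in seq_len(nf)) {
      vol <- cohort_volume(cohort, p, f)
      erb <- segment_erb(vol)
      fm <- segment_markers(vol)
      erb_cen[f, ] <- erb$centroid_mm
      d_cbct[f] <- absolute_centroid_distance(marker_centroid(fm),
                                              erb$centroid_mm)
    }
    ref <- tryCatch(
      select_reference_cbct(d_ct, d_cbct, reference_tolerance_mm),
      igrt_no_reference_error = function(e) NA_integer_)
    cents[[as.character(p)]] <- erb_cen
    if (is.na(ref)) {
      excluded <- c(excluded, p)
    } else {
      refs[as.character(p)] <- ref
      inter[[length(inter) + 1L]] <-
        interfraction_shifts(erb_cen, ref, patient_id = p)
    }
    intra[[length(intra) + 1L]] <-
      intrafraction_shifts(pt$markers_pre, pt$markers_post, patient_id = p)
  }
  list(inter = inter, intra = intra, erb_centroids = cents,
       reference_index = refs, excluded = excluded)
}
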