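#' Containment of the ERB within the planning rectum contour
#'
#' Fraction of the balloon's voxels that lie inside the rectal volume
#' delineated on the planning scan; the quantitative surrogate for the
#' visual "ERB within the rectal contour" check.
#'
#' @param erb_mask logical array (balloon at one fraction).
#' @param rectum_mask logical array (planning rectum), same grid.
#' @return fraction in [0, 1].
#' @export
containment_fraction <- function(erb_mask, rectum_mask) {
  if (!all(dim(erb_mask) == dim(rectum_mask)))
    stop("masks must share the same grid")
  n <- sum(erb_mask != 0)
  if (n == 0L) stop("empty ERB mask")
  sum(erb_mask != 0 & rectum_mask != 0) / n
}

#' Offline adaptive-replanning decision from the first fractions
#'
#' The first four treatment fractions are inspected; if the balloon leaves
#' the planning rectal contour (containment below `threshold`) in at least
#' `min_violations` of them, a new planning CT with adapted contours and
#' plan is indicated. The thresholded rule is this package's operational
#' stand-in for the clinical visual judgement, with deliberately
#' conservative defaults.
#'
#' @param containments numeric vector of exactly 4 containment fractions.
#' @param threshold containment below this counts as a violation.
#' @param min_violations violations needed to trigger adaptation.
#' @param patient_id identifier carried in the result.
#' @return object of class `adapt_decision`: `decision` ("adapt" or "keep"),
#'   `containments`, `n_violations`, rule parameters.
#' @export
adapt_decision <- function(containments, threshold = 0.9,
                           min_violations = 2L, patient_id = NA) {
  containments <- as.numeric(containments)
  if (length(containments) != 4L)
    stop("exactly 4 containment values (first 4 fractions) are required")
  if (any(containments < 0 | containments > 1))
    stop("containment fractions must lie in [0, 1]")
  nv <- sum(containments < threshold)
  structure(list(patient_id = patient_id, containments = containments,
                 n_violations = nv, threshold = threshold,
                 min_violations = as.integer(min_violations),
                 decision = if (nv >= min_violations) "adapt" else "keep"),
            class = "adapt_decision")
}

#' @export
print.adapt_decision <- function(x, ...) {
  cat(sprintf("adapt_decision patient %s: %s (%d/4 fractions below %.2f)\n",
              x$patient_id, x$decision, x$n_violations, x$threshold))
  invisible(x)
}

#' Run the adaptation check on a synthetic cohort
#'
#' Renders and segments each patient's first `n_inspect` fraction scans,
#' computes the ERB containment within the planning rectum contour, and
#' applies [adapt_decision()].
#'
#' @param cohort a `cohort_dataset`.
#' @param patients patient indices (default all).
#' @param n_inspect fractions to inspect (the rule uses 4).
#' @param threshold,min_violations rule parameters.
#' @return data frame: patient, decision, n_violations, min_containment.
#' @export
cohort_adapt_check <- function(cohort, patients = NULL, n_inspect = 4L,
                               threshold = 0.9, min_violations = 2L) {
  if (is.null(patients)) patients <- seq_along(cohort$patients)
  rows <- lapply(patients, function(p) {
    geom <- cohort$patients[[p]]$geometry
    rectum <- geom$structure_masks$rectum
    cont <- vapply(seq_len(n_inspect), function(f) {
      seg <- segment_erb(cohort_volume(cohort, p, f))
      containment_fraction(seg$mask, rectum)
    }, numeric(1L))
    dec <- adapt_decision(cont, threshold, min_violations, patient_id = p)
    data.frame(patient = p, decision = dec$decision,
               n_violations = dec$n_violations,
               min_containment = min(cont))
  })
  do.call(rbind, rows)
}

#' Simulate offline adaptation of a shift series
#'
#' Adaptation acquires a new planning CT, i.e. the patient's systematic
#' offset is re-zeroed while random motion continues. This helper subtracts
#' the given systematic offset from all fractions from `from_fraction`
#' onwards, producing the adapted true shift series.
#'
#' @param series a [shift_series] with known `systematic_mm` (as produced by
#'   [sample_motion()]), or any series plus an explicit `systematic_mm`.
#' @param from_fraction first fraction treated under the adapted plan.
#' @param systematic_mm the offset to remove; defaults to
#'   `series$systematic_mm`.
#' @return the adapted [shift_series].
#' @export
simulate_adaptation <- function(series, from_fraction = 5L,
                                systematic_mm = NULL) {
  stopifnot(inherits(series, "shift_series"))
  if (is.null(systematic_mm)) systematic_mm <- series$systematic_mm
  if (is.null(systematic_mm)) stop("`systematic_mm` is required")
  s <- series$shifts
  rows <- from_fraction:nrow(s)
  s[rows, ] <- sweep(s[rows, , drop = FALSE], 2L, systematic_mm, `-`)
  out <- shift_series(series$patient_id, series$kind, s,
                      series$reference_index)
  out$systematic_mm <- c(0, 0, 0)
  out
}

#' Compare initial and adapted plans
#'
#' Margin tables for the initial and the adapted plan, both combined with
#' the same intrafractional statistics, plus per-axis margin differences
#' (initial minus adapted).
#'
#' @param initial_inter,adapted_inter interfractional [error_stats] of the
#'   two plans.
#' @param intra shared intrafractional [error_stats].
#' @return list: `initial`, `adapted` (margin tables), `delta` (data frame
#'   of per-axis Stroom and van Herk margin reductions in mm).
#' @export
compare_plans <- function(initial_inter, adapted_inter, intra) {
  mi <- margin_report(initial_inter, intra)
  ma <- margin_report(adapted_inter, intra)
  delta <- data.frame(axis = mi$axis,
                      delta_stroom_mm = mi$margin_stroom_mm - ma$margin_stroom_mm,
                      delta_vanherk_mm = mi$margin_vanherk_mm - ma$margin_vanherk_mm)
  list(initial = mi, adapted = ma, delta = delta)
}
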