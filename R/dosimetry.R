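#' Dose grid with fractionation scheme
#'
#' @param volume an [image_volume] carrying dose in Gy (>= 0).
#' @param n_fractions number of fractions.
#' @param dose_per_fraction_gy dose per fraction (Gy).
#' @param prescription_gy total prescription; defaults to
#'   `n_fractions * dose_per_fraction_gy` and must agree with it to 1e-6 Gy.
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(volume, n_fractions = 28L, dose_per_fraction_gy = 1.8,
                      prescription_gy = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  if (any(volume$voxels < 0)) stop("dose must be >= 0 everywhere")
  if (is.null(prescription_gy))
    prescription_gy <- n_fractions * dose_per_fraction_gy
  if (abs(n_fractions * dose_per_fraction_gy - prescription_gy) > 1e-6)
    stop("fraction scheme does not match the prescription")
  structure(list(volume = volume, n_fractions = as.integer(n_fractions),
                 dose_per_fraction_gy = dose_per_fraction_gy,
                 prescription_gy = prescription_gy),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %.1f Gy in %d x %.2f Gy fractions\n",
              x$prescription_gy, x$n_fractions, x$dose_per_fraction_gy))
  print(x$volume)
  invisible(x)
}

#' Sample dose at arbitrary mm points
#'
#' Trilinear interpolation of the dose volume. Points that leave the voxel-
#' centre lattice are handled per `outside`: `"clamp"` (default) samples the
#' edge dose, `"zero"` returns 0. The number of affected points is attached
#' as attribute `n_outside`.
#'
#' @param dose a [dose_grid] or [image_volume].
#' @param points n x 3 matrix of mm coordinates (LR, SI, AP).
#' @param outside out-of-grid policy.
#' @return numeric vector of dose values (Gy) with attribute `n_outside`.
#' @export
sample_dose <- function(dose, points, outside = c("clamp", "zero")) {
  outside <- match.arg(outside)
  vol <- if (inherits(dose, "dose_grid")) dose$volume else dose
  stopifnot(inherits(vol, "image_volume"))
  g <- vol$grid
  f <- mm_to_index(g, points)
  out <- f[, 1] < 1 | f[, 1] > g$shape[1] |
         f[, 2] < 1 | f[, 2] > g$shape[2] |
         f[, 3] < 1 | f[, 3] > g$shape[3]
  fc <- pmin(pmax(f, 1), matrix(g$shape, nrow(f), 3L, byrow = TRUE))
  i0 <- pmin(floor(fc), matrix(g$shape - 1L, nrow(fc), 3L, byrow = TRUE))
  i0 <- pmax(i0, 1)
  t <- fc - i0
  d <- vol$voxels
  n1 <- g$shape[1]; n12 <- g$shape[1] * g$shape[2]
  base <- (i0[, 1]) + (i0[, 2] - 1) * n1 + (i0[, 3] - 1) * n12
  val <- numeric(nrow(fc))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx == 1) t[, 1] else 1 - t[, 1]) *
         (if (dy == 1) t[, 2] else 1 - t[, 2]) *
         (if (dz == 1) t[, 3] else 1 - t[, 3])
    val <- val + w * d[base + dx + dy * n1 + dz * n12]
  }
  if (outside == "zero") val[out] <- 0
  attr(val, "n_outside") <- sum(out)
  val
}

#' Accumulate motion-perturbed dose over a treatment course
#'
#' Rigid isocenter-shift dose model: for every voxel of the structure mask,
#' the course dose is the sum over fractions of the per-fraction weight
#' `dose_per_fraction / prescription` times the static dose sampled at the
#' voxel position displaced by that fraction's shift. With all shifts zero
#' this reproduces the static dose. Shifted sample positions falling outside
#' the grid are clamped to the edge dose and counted in a single warning.
#'
#' @param dose a [dose_grid].
#' @param structure_mask logical array on the dose grid.
#' @param shifts n_fractions x 3 matrix of mm shifts (or a [shift_series]).
#' @return numeric vector of accumulated dose (Gy), one value per structure
#'   voxel (column-major order of `which(structure_mask)`), with attribute
#'   `n_clamped`.
#' @export
accumulate_motion_dose <- function(dose, structure_mask, shifts) {
  stopifnot(inherits(dose, "dose_grid"))
  if (inherits(shifts, "shift_series")) shifts <- shifts$shifts
  shifts <- as_shift_matrix(shifts)
  if (nrow(shifts) != dose$n_fractions)
    stop("one shift per fraction is required")
  g <- dose$volume$grid
  stopifnot(all(dim(structure_mask) == g$shape))
  idx <- which(structure_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty structure mask")
  pts <- index_to_mm(g, idx)
  w <- dose$dose_per_fraction_gy / dose$prescription_gy
  acc <- numeric(nrow(pts))
  n_clamped <- 0L
  for (f in seq_len(nrow(shifts))) {
    sf <- shifts[f, ]
    if (all(sf == 0)) {
      v <- dose$volume$voxels[which(structure_mask != 0)]
      acc <- acc + w * v
    } else {
      v <- sample_dose(dose, sweep(pts, 2L, sf, `+`), outside = "clamp")
      n_clamped <- n_clamped + attr(v, "n_outside")
      acc <- acc + w * as.numeric(v)
    }
  }
  if (n_clamped > 0L)
    warning(sprintf("%d shifted sample positions were clamped to the grid edge",
                    n_clamped), call. = FALSE)
  attr(acc, "n_clamped") <- n_clamped
  acc
}

#' Cumulative dose-volume histogram
#'
#' Volume fraction of the structure receiving at least each dose level, on a
#' fixed bin grid (default 0 to 59.5 Gy in 0.5 Gy steps, 120 points).
#'
#' @param dose_values_gy per-voxel dose values of one structure.
#' @param bin_width_gy dose resolution.
#' @param max_dose_gy last bin edge; default 59.5 Gy.
#' @return object of class `dvh_curve`: `dose_gy` (bin edges) and
#'   `volume_pct` (cumulative volume, percent).
#' @export
compute_dvh <- function(dose_values_gy, bin_width_gy = 0.5,
                        max_dose_gy = 59.5) {
  v <- as.numeric(dose_values_gy)
  if (length(v) == 0L) stop("no dose values")
  if (bin_width_gy <= 0) stop("`bin_width_gy` must be > 0")
  bins <- seq(0, max_dose_gy, by = bin_width_gy)
  pct <- vapply(bins, function(t) 100 * mean(v >= t), numeric(1L))
  structure(list(dose_gy = bins, volume_pct = pct), class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve: %d points, %.1f-%.1f Gy\n", length(x$dose_gy),
              min(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}

#' Mean DVH across patients with per-bin dispersion
#'
#' @param curves list of >= 2 [compute_dvh()] results on identical bin grids.
#' @return a `dvh_curve` with additional element `sd_pct` (per-bin sample SD
#'   across patients).
#' @export
mean_dvh <- function(curves) {
  if (length(curves) < 2L)
    stop("per-bin SD requires at least 2 curves")
  bins <- curves[[1L]]$dose_gy
  for (c in curves[-1L])
    if (!isTRUE(all.equal(c$dose_gy, bins)))
      stop("all curves must share the same bin grid")
  m <- do.call(rbind, lapply(curves, `[[`, "volume_pct"))
  structure(list(dose_gy = bins, volume_pct = colMeans(m),
                 sd_pct = apply(m, 2L, stats::sd)),
            class = "dvh_curve")
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on paired samples (e.g. per-bin DVH values of
#' a motion-perturbed vs a static plan). Zero differences are removed first;
#' if none remain the result is degenerate with p = 1. For
#' n <= `exact_max_n` the exact p-value is computed by enumerating all 2^n
#' sign assignments of the (tie-averaged) ranks; for larger n the normal
#' approximation with continuity and tie correction is used.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alpha significance level for the `significant` flag.
#' @param exact_max_n largest n for the exact enumeration.
#' @return list: `statistic` (V, sum of positive ranks), `p_value`, `n`
#'   (pairs after zero removal), `significant`, `degenerate`, `method`.
#' @export
paired_signed_rank_test <- function(a, b, alpha = 0.05, exact_max_n = 12L) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p_value = 1.0, n = 0L,
                significant = FALSE, degenerate = TRUE,
                method = "degenerate (all differences zero)"))
  if (n < 5L)
    warning("fewer than 5 non-zero differences; the signed-rank test has very low power",
            call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # subset-sum doubling enumerates the V statistic of all 2^n assignments
    sums <- 0
    for (i in seq_len(n)) sums <- c(sums, sums + r[i])
    eps <- 1e-9
    p <- min(1, 2 * min(mean(sums <= V + eps), mean(sums >= V - eps)))
    method <- "exact enumeration"
  } else {
    ht <- stats::wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE)
    p <- ht$p.value
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n = n,
       significant = p < alpha, degenerate = FALSE, method = method)
}

#' Dosimetric impact of measured motion on a structure
#'
#' Convenience wrapper reproducing the plan-vs-motion comparison for a
#' cohort: per patient, accumulates static (zero-shift) and motion-perturbed
#' dose in the structure, computes both DVHs, averages them across patients,
#' and compares the mean curves per dose bin with the paired signed-rank
#' test. The comparison drops the final bin of the grid, giving the
#' conventional 119 points at 0.5 Gy resolution.
#'
#' @param dose a [dose_grid].
#' @param structure_mask logical array.
#' @param shifts_list list (one per patient) of n_fractions x 3 composed
#'   shift matrices.
#' @param alpha significance level.
#' @param drop_last_bin drop the final DVH bin before testing.
#' @return list: `dvh_static`, `dvh_motion` (mean curves), `test`
#'   (signed-rank result), `per_patient` (list of static/motion curves).
#' @export
motion_dose_impact <- function(dose, structure_mask, shifts_list,
                               alpha = 0.05, drop_last_bin = TRUE) {
  zero <- matrix(0, dose$n_fractions, 3L)
  static_curves <- list(); motion_curves <- list()
  for (i in seq_along(shifts_list)) {
    acc0 <- accumulate_motion_dose(dose, structure_mask, zero)
    acc1 <- accumulate_motion_dose(dose, structure_mask, shifts_list[[i]])
    static_curves[[i]] <- compute_dvh(acc0)
    motion_curves[[i]] <- compute_dvh(acc1)
  }
  ds <- if (length(static_curves) > 1L) mean_dvh(static_curves)
        else static_curves[[1L]]
  dm <- if (length(motion_curves) > 1L) mean_dvh(motion_curves)
        else motion_curves[[1L]]
  keep <- seq_len(length(ds$dose_gy) - if (drop_last_bin) 1L else 0L)
  test <- suppressWarnings(
    paired_signed_rank_test(dm$volume_pct[keep], ds$volume_pct[keep],
                            alpha = alpha))
  list(dvh_static = ds, dvh_motion = dm, test = test,
       per_patient = list(static = static_curves, motion = motion_curves))
}
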