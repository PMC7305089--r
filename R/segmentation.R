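#' Default segmentation thresholds for a volume
#'
#' Calibration-free thresholds: markers are brighter than the midpoint
#' between the median (background) intensity and the maximum; the air-filled
#' ERB is darker than the midpoint between the median and the minimum.
#'
#' @param volume an [image_volume].
#' @return list with `high` (marker) and `low` (ERB) thresholds.
#' @export
default_thresholds <- function(volume) {
  med <- stats::median(volume$voxels)
  list(high = (med + max(volume$voxels)) / 2,
       low = (med + min(volume$voxels)) / 2)
}

#' Segment fiducial markers from a volume
#'
#' Thresholds the volume at `high_threshold`, labels 26-connected components
#' (so fragments separated by less than one full background voxel — i.e.
#' diagonal-adjacent — stay one marker), filters them to `size_range`
#' voxels, and returns unweighted voxel-centre centroids in mm, canonically
#' ordered by SI, then LR, then AP coordinate.
#'
#' @param volume an [image_volume].
#' @param high_threshold intensity above which a voxel is marker candidate;
#'   default from [default_thresholds()].
#' @param size_range admissible component size in voxels, `c(min, max)`.
#' @param expected_count expected number of markers (default 3); a mismatch
#'   raises a condition of class `igrt_marker_count_error` carrying the found
#'   count, or `NA` to skip the check.
#' @return object of class `marker_set`: `centroids` (n x 3 mm matrix),
#'   `voxel_counts`, `grid`.
#' @export
segment_markers <- function(volume, high_threshold = NULL,
                            size_range = c(4L, 250L), expected_count = 3L) {
  stopifnot(inherits(volume, "image_volume"))
  if (is.null(high_threshold)) high_threshold <- default_thresholds(volume)$high
  if (high_threshold < min(volume$voxels))
    stop("`high_threshold` lies below the volume minimum; every voxel would be a marker candidate")
  mask <- volume$voxels > high_threshold
  lab <- label_components(mask, connectivity = 26L)
  ids <- sort(unique(lab[lab > 0L]))
  comp <- lapply(ids, function(k) which(lab == k, arr.ind = TRUE))
  sizes <- vapply(comp, nrow, integer(1L))
  keep <- sizes >= size_range[1] & sizes <= size_range[2]
  comp <- comp[keep]; sizes <- sizes[keep]
  found <- length(comp)
  if (!is.na(expected_count) && found != expected_count)
    stop(errorCondition(
      sprintf("expected %d markers but found %d", expected_count, found),
      class = c("igrt_marker_count_error", "error", "condition"),
      count = found))
  if (found == 0L)
    return(structure(list(centroids = as_shift_matrix(matrix(0, 0, 3)),
                          voxel_counts = integer(0), grid = volume$grid),
                     class = "marker_set"))
  cen <- t(vapply(comp, function(ix) colMeans(index_to_mm(volume$grid, ix)),
                  numeric(3L)))
  ord <- order(cen[, 2L], cen[, 1L], cen[, 3L])
  structure(list(centroids = as_shift_matrix(cen[ord, , drop = FALSE]),
                 voxel_counts = sizes[ord], grid = volume$grid),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers\n", nrow(x$centroids)))
  print(round(x$centroids, 3))
  invisible(x)
}

#' Segment the endorectal balloon from a volume
#'
#' Selects the largest 26-connected component below `low_threshold`
#' (optionally restricted to an ROI mask), fills interior holes, and reports
#' centroid, volume, equivalent diameter and per-axis extents.
#'
#' @param volume an [image_volume].
#' @param low_threshold intensity below which a voxel is balloon candidate;
#'   default from [default_thresholds()].
#' @param roi_mask optional logical array restricting the search.
#' @return object of class `erb_segment`: `centroid_mm`, `volume_mm3`,
#'   `equivalent_diameter_mm`, `extent_mm` (2 x 3), `voxel_count`, `mask`,
#'   `grid`.
#' @export
segment_erb <- function(volume, low_threshold = NULL, roi_mask = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  if (is.null(low_threshold)) low_threshold <- default_thresholds(volume)$low
  mask <- volume$voxels < low_threshold
  if (!is.null(roi_mask)) {
    stopifnot(all(dim(roi_mask) == volume$grid$shape))
    mask <- mask & (roi_mask != 0)
  }
  lab <- label_components(mask, connectivity = 26L)
  if (max(lab) == 0L)
    stop(errorCondition("no component below the ERB threshold",
                        class = c("igrt_erb_not_found_error", "error",
                                  "condition")))
  sizes <- tabulate(lab[lab > 0L])
  erb <- fill_holes(lab == which.max(sizes))
  idx <- which(erb, arr.ind = TRUE)
  mm <- index_to_mm(volume$grid, idx)
  n <- nrow(idx)
  vol <- n * voxel_volume_mm3(volume$grid)
  ext <- rbind(apply(mm, 2L, min) - volume$grid$spacing / 2,
               apply(mm, 2L, max) + volume$grid$spacing / 2)
  dimnames(ext) <- list(c("min", "max"), axis_names())
  structure(list(centroid_mm = stats::setNames(colMeans(mm), axis_names()),
                 volume_mm3 = vol,
                 equivalent_diameter_mm = (6 * vol / pi)^(1 / 3),
                 extent_mm = ext, voxel_count = n, mask = erb,
                 grid = volume$grid),
            class = "erb_segment")
}

#' @export
print.erb_segment <- function(x, ...) {
  cat(sprintf(
    "erb_segment: %.0f mm^3 (%d voxels), eq. diameter %.1f mm, centroid (%s) mm\n",
    x$volume_mm3, x$voxel_count, x$equivalent_diameter_mm,
    paste(sprintf("%.2f", x$centroid_mm), collapse = ", ")))
  invisible(x)
}

#' Pairwise inter-marker distances
#'
#' Euclidean distances between the three markers under the canonical
#' ordering: pairs (1,2), (1,3), (2,3). Stable inter-marker distances across
#' fractions indicate absence of marker migration.
#'
#' @param markers a [marker_set] (or 3 x 3 matrix of mm positions) with
#'   exactly 3 markers.
#' @return named numeric vector of 3 distances (mm).
#' @export
inter_marker_distances <- function(markers) {
  cen <- if (inherits(markers, "marker_set")) markers$centroids
         else as_shift_matrix(markers)
  if (nrow(cen) != 3L)
    stop(errorCondition(
      sprintf("inter-marker distances require exactly 3 markers, got %d",
              nrow(cen)),
      class = c("igrt_marker_arity_error", "error", "condition"),
      count = nrow(cen)))
  d <- function(i, j) sqrt(sum((cen[i, ] - cen[j, ])^2))
  c(d12 = d(1, 2), d13 = d(1, 3), d23 = d(2, 3))
}

#' Centroid of a marker set
#'
#' Arithmetic mean of the marker positions per coordinate, the FM surrogate
#' for the target position.
#'
#' @param markers a [marker_set] or n x 3 matrix of mm positions (n >= 1).
#' @return mm triple (LR, SI, AP).
#' @export
marker_centroid <- function(markers) {
  cen <- if (inherits(markers, "marker_set")) markers$centroids
         else as_shift_matrix(markers)
  if (nrow(cen) < 1L) stop("at least one marker is required")
  stats::setNames(colMeans(cen), axis_names())
}
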