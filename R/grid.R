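#' Regular 3D sampling grid
#'
#' A `grid_spec` describes the voxel lattice shared by all volumes in an
#' analysis: the number of voxels per axis, the voxel size in mm, and the mm
#' coordinate of the centre of voxel (1,1,1). Axes follow the package-wide
#' patient frame: axis 1 = LR (+ left), axis 2 = SI (+ superior),
#' axis 3 = AP (+ anterior).
#'
#' @param shape integer vector of length 3, voxel counts per axis (>= 1).
#' @param spacing numeric vector of length 3 (or scalar), mm per voxel (> 0).
#' @param origin mm coordinates of the centre of voxel (1,1,1). Default
#'   centres the grid on (0, 0, 0).
#' @return An object of class `grid_spec` with elements `shape`, `spacing`,
#'   `origin`.
#' @examples
#' g <- grid_spec(c(96, 96, 64), 2)
#' grid_extent(g)
#' @export
grid_spec <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive voxel counts")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite")
  if (is.null(origin)) origin <- -(shape - 1L) * spacing / 2
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin))) stop("`origin` must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %s voxels, %s mm spacing, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel-centre coordinates along one axis
#' @param grid a [grid_spec].
#' @param axis axis index (1 = LR, 2 = SI, 3 = AP).
#' @return numeric vector of mm coordinates of voxel centres.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Physical extent of a grid
#' @param grid a [grid_spec].
#' @return 2x3 matrix with the min/max voxel-centre coordinate per axis (mm).
#' @export
grid_extent <- function(grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1L) * grid$spacing
  m <- rbind(lo, hi)
  dimnames(m) <- list(c("min", "max"), c("LR", "SI", "AP"))
  m
}

#' Convert voxel indices to mm coordinates
#' @param grid a [grid_spec].
#' @param index n x 3 matrix of 1-based (possibly fractional) voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
index_to_mm <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3L)
  sweep(sweep(index - 1, 2L, grid$spacing, `*`), 2L, grid$origin, `+`)
}

#' Convert mm coordinates to fractional voxel indices
#' @param grid a [grid_spec].
#' @param mm n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of 1-based fractional voxel indices.
#' @export
mm_to_index <- function(grid, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3L)
  sweep(sweep(mm, 2L, grid$origin, `-`), 2L, grid$spacing, `/`) + 1
}

#' 3D scalar image volume
#'
#' The carrier type for planning CT, CBCT-like and dose volumes: a 3D array
#' of finite scalars plus its [grid_spec].
#'
#' @param voxels 3D numeric (or logical) array.
#' @param grid a [grid_spec] whose `shape` matches `dim(voxels)`.
#' @return An object of class `image_volume` with elements `voxels`, `grid`.
#' @export
image_volume <- function(voxels, grid) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec")
  if (!all(dim(voxels) == grid$shape))
    stop("array dimensions do not match the grid shape")
  if (is.logical(voxels)) storage.mode(voxels) <- "integer"
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("voxel values must be finite")
  structure(list(voxels = voxels, grid = grid), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  r <- range(x$voxels)
  cat(sprintf("image_volume: %s voxels at %s mm, range [%.4g, %.4g]\n",
              paste(x$grid$shape, collapse = "x"),
              paste(format(x$grid$spacing), collapse = "x"), r[1], r[2]))
  invisible(x)
}

#' Voxel volume of a grid in cubic mm
#' @param grid a [grid_spec].
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

# mm centroid of a logical mask (unweighted mean of voxel centres)
mask_centroid_mm <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid")
  colMeans(index_to_mm(grid, idx))
}

axis_names <- function() c("LR", "SI", "AP")

as_shift_matrix <- function(x) {
  x <- matrix(as.numeric(x), ncol = 3L)
  colnames(x) <- axis_names()
  x
}
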