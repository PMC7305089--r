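# Connected-component machinery for binary 3D masks.
#
# Labelling uses iterative minimum-label propagation on a zero-padded copy of
# the mask, fully vectorised over the foreground voxels. Each sweep replaces a
# voxel's label with the minimum over its (6- or 26-) neighbourhood; at the
# fixed point every component carries the linear index of its smallest voxel,
# which is then remapped to 1..K in first-voxel order.

neighbour_offsets <- function(dims, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  d <- d[!(d$di == 0 & d$dj == 0 & d$dk == 0), , drop = FALSE]
  if (connectivity == 6L)
    d <- d[abs(d$di) + abs(d$dj) + abs(d$dk) == 1L, , drop = FALSE]
  d$di + d$dj * dims[1] + d$dk * dims[1] * dims[2]
}

pad_mask <- function(mask) {
  dm <- dim(mask)
  p <- array(FALSE, dm + 2L)
  p[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- mask
  p
}

unpad <- function(p) {
  dm <- dim(p) - 2L
  p[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)]
}

#' Label connected components of a binary 3D mask
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (default; face, edge and corner neighbours) or 6
#'   (face neighbours only).
#' @return Integer array of the same shape: 0 for background, components
#'   labelled 1..K in order of their first voxel (column-major scan).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- mask != 0
  p <- pad_mask(mask)
  fg <- which(p)
  lab <- integer(length(p))
  out <- array(0L, dim(mask))
  if (length(fg) == 0L) return(out)
  off <- neighbour_offsets(dim(p), as.integer(connectivity))
  lab[fg] <- fg
  repeat {
    cur <- lab[fg]
    m <- cur
    for (o in off) {
      nb <- lab[fg + o]
      nz <- nb != 0L
      if (any(nz)) m[nz] <- pmin(m[nz], nb[nz])
    }
    if (all(m == cur)) break
    lab[fg] <- m
  }
  roots <- lab[fg]
  ids <- unique(roots)                      # `which` order => first-voxel order
  relab <- integer(max(ids))
  relab[ids] <- seq_along(ids)
  labp <- array(0L, dim(p))
  labp[fg] <- relab[roots]
  out[] <- unpad(labp)
  out
}

#' Fill interior holes of a binary mask
#'
#' Background voxels (6-connected) that cannot reach the array border are
#' interior holes and are set to foreground. Computation is restricted to the
#' bounding box of the mask for speed.
#'
#' @param mask 3D logical array.
#' @return logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- mask != 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mask)
  dm <- dim(mask)
  lo <- pmax(apply(idx, 2L, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2L, max) + 1L, dm)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  bg <- label_components(!sub, connectivity = 6L)
  ds <- dim(sub)
  border <- unique(c(bg[c(1L, ds[1]), , ], bg[, c(1L, ds[2]), ], bg[, , c(1L, ds[3])]))
  border <- border[border != 0L]
  holes <- bg != 0L & !(bg %in% border)
  sub[holes] <- TRUE
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  mask
}
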