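# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# compact phantom: same anatomy at roughly half scale, renders ~5x faster
small_grid <- function() grid_spec(c(48L, 48L, 48L), 2)

small_config <- function(...) {
  defaults <- list(erb_center = c(0, 0, -20),
                   erb_semi_axes = c(12, 16, 10),
                   rectum_clearance_mm = c(3, 4, 3),
                   wall_thickness_mm = 3,
                   ctv_center = c(0, 1, 4),
                   ctv_semi_axes = c(10, 9, 7),
                   ptv_margin_mm = c(4, 5, 4),
                   marker_offsets = rbind(c(-5, -5, 0), c(5, -5, 1),
                                          c(0, 6, -1)),
                   marker_jitter_sd_mm = 0.5,
                   marker_min_separation_mm = 6)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# millimetre-scale phantom on a 1 mm grid for exact-translation checks
mm_grid <- function() grid_spec(c(40L, 40L, 40L), 1)

mm_config <- function(...) {
  defaults <- list(erb_center = c(0, 0, -8),
                   erb_semi_axes = c(8, 10, 7),
                   rectum_clearance_mm = c(2, 2, 2),
                   wall_thickness_mm = 2,
                   ctv_center = c(0, 1, 4),
                   ctv_semi_axes = c(6, 5, 4),
                   ptv_margin_mm = c(2, 2, 2),
                   marker_offsets = rbind(c(-3, -3, 0), c(3, -3, 1),
                                          c(0, 4, -1)),
                   marker_jitter_sd_mm = 0.3,
                   marker_min_separation_mm = 4,
                   marker_radius_mm = 1.5)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# --- independent oracles ----------------------------------------------------

# queue-based flood fill, the reference for label_components
flood_fill_labels <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  nb <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  nb <- nb[!(nb$di == 0 & nb$dj == 0 & nb$dk == 0), ]
  if (connectivity == 6L)
    nb <- nb[abs(nb$di) + abs(nb$dj) + abs(nb$dk) == 1L, ]
  lab <- array(0L, dm)
  k <- 0L
  for (lin in which(mask != 0)) {
    if (lab[lin] != 0L) next
    k <- k + 1L
    queue <- lin
    lab[lin] <- k
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      ci <- arrayInd(cur, dm)
      for (r in seq_len(nrow(nb))) {
        p <- ci + c(nb$di[r], nb$dj[r], nb$dk[r])
        if (any(p < 1L) || any(p > dm)) next
        l2 <- p[1] + (p[2] - 1L) * dm[1] + (p[3] - 1L) * dm[1] * dm[2]
        if (mask[l2] != 0 && lab[l2] == 0L) {
          lab[l2] <- k
          queue <- c(queue, l2)
        }
      }
    }
  }
  lab
}

# label arrays agree up to renaming iff the induced partitions coincide
same_partition <- function(a, b) {
  fa <- as.integer(a[a != 0 | b != 0])
  fb <- as.integer(b[a != 0 | b != 0])
  if (any(xor(fa == 0L, fb == 0L))) return(FALSE)
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(paste(fa, fb))) == length(unique(fb))
}

# scalar trilinear interpolation by sequential 1D lerps
trilinear_reference <- function(vol, p) {
  g <- vol$grid
  f <- (p - g$origin) / g$spacing + 1
  i0 <- pmin(pmax(floor(f), 1), g$shape - 1L)
  t <- f - i0
  lerp <- function(a, b, w) a * (1 - w) + b * w
  c00 <- lerp(vol$voxels[i0[1], i0[2], i0[3]],
              vol$voxels[i0[1] + 1, i0[2], i0[3]], t[1])
  c10 <- lerp(vol$voxels[i0[1], i0[2] + 1, i0[3]],
              vol$voxels[i0[1] + 1, i0[2] + 1, i0[3]], t[1])
  c01 <- lerp(vol$voxels[i0[1], i0[2], i0[3] + 1],
              vol$voxels[i0[1] + 1, i0[2], i0[3] + 1], t[1])
  c11 <- lerp(vol$voxels[i0[1], i0[2] + 1, i0[3] + 1],
              vol$voxels[i0[1] + 1, i0[2] + 1, i0[3] + 1], t[1])
  lerp(lerp(c00, c10, t[2]), lerp(c01, c11, t[2]), t[3])
}

# exact two-sided signed-rank p by explicit loop over all sign assignments
signed_rank_enumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}

# plant a spherical blob of given intensity into an array (voxel centres
# within radius of the mm position)
plant_blob <- function(vox, grid, center_mm, radius_mm, value) {
  u <- (axis_coords(grid, 1L) - center_mm[1])^2
  v <- (axis_coords(grid, 2L) - center_mm[2])^2
  w <- (axis_coords(grid, 3L) - center_mm[3])^2
  vox[outer(outer(u, v, `+`), w, `+`) <= radius_mm^2] <- value
  vox
}
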