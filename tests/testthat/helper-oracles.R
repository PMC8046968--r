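# Independent brute-force oracles and tiny fixture builders.
# Everything here is deliberately naive (loops, O(N*M) scans) so it cannot
# share a code path with the implementation under test.

# 26-neighbourhood boundary scan over a small label array
bf_boundary <- function(lab) {
  d <- dim(lab)
  out <- array(FALSE, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    l <- lab[x, y, z]
    if (l <= 0) next
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3] || lab[x2, y2, z2] != l) {
        out[x, y, z] <- TRUE
      }
    }
  }
  out
}

# min distance from each query point (rows) to a point set (rows), O(N*M)
bf_nearest <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i)
    sqrt(min(colSums((t(ref) - query[i, ])^2))), numeric(1))
}

# brute-force distance field at every voxel center of a mask's grid
bf_distance_field <- function(mask, voxel_size) {
  d <- dim(mask)
  ref <- (arrayInd(which(mask), d) - 1) * voxel_size
  grid <- (arrayInd(seq_len(prod(d)), d) - 1) * voxel_size
  array(bf_nearest(grid, ref), dim = d)
}

# spherical lumen label volume centred at voxel index `center` (1-based)
make_sphere_label <- function(dims, center, r_vox, label = 1L,
                              lab = array(0L, dims)) {
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    if (sum((c(x, y, z) - center)^2) <= r_vox^2) lab[x, y, z] <- label
  }
  lab
}

# straight fibril along +x starting at p0
straight_fibril <- function(p0, len, n = 2, id = "s", radius = 5) {
  xs <- seq(0, len, length.out = n)
  fibril(cbind(p0[1] + xs, p0[2], p0[3]), id = id, radius = radius)
}

# union membrane voxel mask of a scene (mirrors the internal convention)
.membrane_mask_for_test <- function(scene) {
  d <- dim(scene$label_volume)
  mask <- array(FALSE, d)
  for (m in scene$membrane_points)
    mask[round(m / scene$voxel_size) + 1] <- TRUE
  mask
}

# small two-sphere scene used across spatial tests
two_sphere_scene <- function(voxel_size = 2, dims = c(90, 40, 40),
                             r1 = 15, r2 = 20, gap_vox = 10) {
  c1 <- c(20, 20, 20)
  c2 <- c(20 + r1 + gap_vox + r2, 20, 20)
  lab <- make_sphere_label(dims, c1, r1, 1L)
  lab <- make_sphere_label(dims, c2, r2, 2L, lab)
  tomogram_scene(lab, voxel_size = voxel_size)
}
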