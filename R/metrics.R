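#' Cytosolic fibril density
#'
#' Fraction of cytosolic volume occupied by fibrils. The cell volume is the
#' full X.Y grid extent times the lamella thickness; the cytosolic volume
#' subtracts the lumina of all organelles (labelled voxels times
#' voxel_size^3). Fibril volume approximates each fibril by a solid
#' cylinder of its radius: `sum(pi * r^2 * L)`. Overlapping fibrils are not
#' de-duplicated; volumes add linearly.
#'
#' @param scene a [tomogram_scene()].
#' @param fibrils list of [fibril()] (may be empty).
#' @return object of class `density_result`: `cytosolic_volume_nm3`,
#'   `fibril_volume_nm3`, `density`, `n_fibrils`, `tomogram`.
#' @param tomogram optional tomogram id carried through to outputs.
#' @export
#' @examples
#' sc <- tomogram_scene(array(0L, c(20, 20, 15)), voxel_size = 10)
#' f <- fibril(rbind(c(0, 0, 0), c(150, 0, 0)))
#' cytosolic_fibril_density(sc, list(f))$density
cytosolic_fibril_density <- function(scene, fibrils, tomogram = NA_character_) {
  stopifnot(inherits(scene, "tomogram_scene"))
  cell_vol <- scene$extent[1] * scene$extent[2] * scene$lamella_thickness
  lumen_vol <- sum(scene$label_volume > 0L) * scene$voxel_size^3
  cyto <- cell_vol - lumen_vol
  if (cyto <= 0)
    .stopf("cytosolic volume is non-positive (lumina fill the lamella)",
           class = "fibrilstats_config_error")
  fib_vol <- 0
  if (length(fibrils))
    fib_vol <- sum(vapply(fibrils, function(f)
      pi * f$radius^2 * fibril_length(f), numeric(1)))
  structure(list(cytosolic_volume_nm3 = unname(cyto),
                 fibril_volume_nm3 = fib_vol,
                 density = unname(fib_vol / cyto),
                 n_fibrils = length(fibrils),
                 tomogram = tomogram),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("density_result: %d fibrils, density %.3e (fibril %.3e / cytosol %.3e nm^3)\n",
              x$n_fibrils, x$density, x$fibril_volume_nm3,
              x$cytosolic_volume_nm3))
  invisible(x)
}

#' Gold-label periodicity in beta-strand units
#'
#' Converts the mean center-to-center distance between gold beads decorating
#' a fibril into the number of beta-strands per label, using the axial
#' strand spacing of the amyloid fold (~4.8 Angstrom).
#'
#' @param mean_gold_distance mean bead spacing in Angstrom (> 0).
#' @param strand_spacing beta-strand repeat in Angstrom (default 4.8).
#' @return strands per label (float).
#' @export
#' @examples
#' gold_label_periodicity(35)  # ~7.3: roughly every 7th-8th strand
gold_label_periodicity <- function(mean_gold_distance, strand_spacing = 4.8) {
  if (!is.numeric(mean_gold_distance) || !is.numeric(strand_spacing) ||
      mean_gold_distance <= 0 || strand_spacing <= 0)
    .stopf("both distances must be positive (Angstrom)",
           class = "fibrilstats_domain_error")
  mean_gold_distance / strand_spacing
}

#' Fibril length histogram table
#'
#' @param fibrils list of [fibril()].
#' @param bin_width bin width in nm.
#' @param max_length upper edge in nm (lengths above are clamped into the
#'   last bin).
#' @return data.frame with `bin_left`, `bin_right`, `count`.
#' @export
length_histogram <- function(fibrils, bin_width = 50, max_length = 1000) {
  lens <- vapply(fibrils, fibril_length, numeric(1))
  edges <- seq(0, max_length, by = bin_width)
  idx <- pmin(pmax(findInterval(lens, edges, rightmost.closed = TRUE), 1L),
              length(edges) - 1L)
  data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
             count = tabulate(idx, nbins = length(edges) - 1L))
}

#' Voxelized density cross-check
#'
#' Counts the voxels of a scene whose centers lie within `radius` of any
#' fibril centerline segment, with the orthogonal projection required to
#' fall on the segment (open cylinder: the spherical end caps are excluded
#' so the count estimates the same `pi r^2 L` convention as the analytic
#' sum), and converts the count into a volume fraction of the cytosol.
#' Intended as a discretization cross-check on small scenes;
#' O(n_voxels x n_segments).
#'
#' @param scene a [tomogram_scene()].
#' @param fibrils list of [fibril()].
#' @return voxel-count density (dimensionless).
#' @export
voxelized_fibril_density <- function(scene, fibrils) {
  d <- dim(scene$label_volume)
  vs <- scene$voxel_size
  ax <- (seq_len(d[1]) - 1) * vs
  ay <- (seq_len(d[2]) - 1) * vs
  az <- (seq_len(d[3]) - 1) * vs
  vox <- cbind(rep(ax, times = d[2] * d[3]),
               rep(rep(ay, each = d[1]), times = d[3]),
               rep(az, each = d[1] * d[2]))
  inside <- rep(FALSE, nrow(vox))
  for (f in fibrils) {
    p <- f$points
    r2 <- f$radius^2
    for (s in seq_len(nrow(p) - 1)) {
      a <- p[s, ]; b <- p[s + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      ap <- sweep(vox, 2, a)
      t <- as.numeric(ap %*% ab) / len2
      on_seg <- t >= 0 & t <= 1
      dd <- ap - outer(t, ab)
      inside <- inside | (on_seg & rowSums(dd^2) <= r2)
    }
  }
  cyto_vox <- sum(scene$label_volume == 0L)
  sum(inside & as.vector(scene$label_volume == 0L)) / cyto_vox
}
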