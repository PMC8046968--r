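#' Euclidean distance field to the organelle membranes
#'
#' Exact Euclidean distance transform (voxel-center metric) of the union of
#' all membrane voxels of a scene, in nm. When the scene carries explicit
#' membrane point sets that did not originate from the label volume, points
#' are rasterized to their nearest voxel first.
#'
#' @param scene a [tomogram_scene()] with at least one membrane point.
#' @return object of class `distance_field`: 3D array of distances (nm)
#'   plus `voxel_size`.
#' @export
membrane_distance_field <- function(scene) {
  stopifnot(inherits(scene, "tomogram_scene"))
  mask <- .membrane_mask(scene)
  if (!any(mask))
    .stopf("scene has no membrane voxels", class = "fibrilstats_error")
  d <- dim(scene$label_volume)
  sq <- .edt3d_sq(as.logical(mask), d)
  field <- array(sqrt(sq) * scene$voxel_size, dim = d)
  structure(list(field = field, voxel_size = scene$voxel_size),
            class = "distance_field")
}

# union membrane voxel mask from the scene's per-organelle point sets
.membrane_mask <- function(scene, exclude = NULL) {
  d <- dim(scene$label_volume)
  mask <- array(FALSE, d)
  mp <- scene$membrane_points
  if (!is.null(exclude)) mp <- mp[setdiff(names(mp), as.character(exclude))]
  for (m in mp) {
    ijk <- round(m / scene$voxel_size) + 1L
    ijk[, 1] <- pmin(pmax(ijk[, 1], 1L), d[1])
    ijk[, 2] <- pmin(pmax(ijk[, 2], 1L), d[2])
    ijk[, 3] <- pmin(pmax(ijk[, 3], 1L), d[3])
    mask[ijk] <- TRUE
  }
  mask
}

# Trilinear interpolation of a voxel-center field at world points (nm).
# Points must lie within the voxel-center bounds [0, (n-1)*voxel_size].
.interp_trilinear <- function(field, voxel_size, pts) {
  d <- dim(field)
  g <- pts / voxel_size
  hi <- matrix(rep(d - 1, each = nrow(g)), ncol = 3)
  if (any(g < -1e-9) || any(g > hi + 1e-9))
    .stopf("point outside the field grid", class = "fibrilstats_error")
  g <- pmin(pmax(g, 0), hi)
  i0 <- pmax(pmin(floor(g), hi - 1), 0)
  f <- g - i0
  i0 <- i0 + 1L  # to 1-based
  ix <- i0[, 1]; iy <- i0[, 2]; iz <- i0[, 3]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  at <- function(dx, dy, dz)
    field[cbind(ix + dx, iy + dy, iz + dz)]
  c000 <- at(0L, 0L, 0L); c100 <- at(1L, 0L, 0L)
  c010 <- at(0L, 1L, 0L); c110 <- at(1L, 1L, 0L)
  c001 <- at(0L, 0L, 1L); c101 <- at(1L, 0L, 1L)
  c011 <- at(0L, 1L, 1L); c111 <- at(1L, 1L, 1L)
  (c000 * (1 - fx) + c100 * fx) * (1 - fy) * (1 - fz) +
    (c010 * (1 - fx) + c110 * fx) * fy * (1 - fz) +
    (c001 * (1 - fx) + c101 * fx) * (1 - fy) * fz +
    (c011 * (1 - fx) + c111 * fx) * fy * fz
}

#' Fibril-to-membrane nearest distances
#'
#' One distance per fibril point: the membrane distance field interpolated
#' trilinearly at the point's world coordinates. Fibrils are resampled at
#' `step` (default: the voxel size) so the point spacing matches the field
#' resolution; pass `resample = FALSE` when the fibrils are already
#' resampled.
#'
#' @param fibrils list of [fibril()].
#' @param field a [membrane_distance_field()].
#' @param step resampling step in nm.
#' @param resample resample fibrils before sampling the field?
#' @return data.frame with `fibril_id`, `distance_nm`.
#' @export
fibril_membrane_distances <- function(fibrils, field,
                                      step = field$voxel_size,
                                      resample = TRUE) {
  stopifnot(inherits(field, "distance_field"))
  if (!length(fibrils))
    return(data.frame(fibril_id = character(0), distance_nm = numeric(0)))
  if (resample)
    fibrils <- lapply(fibrils, function(f)
      suppressWarnings(resample_polyline(f, step)))
  npts <- vapply(fibrils, function(f) nrow(f$points), integer(1))
  ids <- vapply(fibrils, function(f) f$id, character(1))
  pts <- do.call(rbind, lapply(fibrils, `[[`, "points"))
  dists <- tryCatch(
    .interp_trilinear(field$field, field$voxel_size, pts),
    error = function(e) {
      # identify the offender for the error message
      for (f in fibrils) {
        ok <- tryCatch({
          .interp_trilinear(field$field, field$voxel_size, f$points); TRUE
        }, error = function(e2) FALSE)
        if (!ok)
          .stopf("fibril %s has points outside the tomogram grid", f$id,
                 class = "fibrilstats_error")
      }
      .stopf("fibril points outside the tomogram grid",
             class = "fibrilstats_error")
    })
  data.frame(fibril_id = rep(ids, npts), distance_nm = dists)
}

#' Inter-membrane nearest distances
#'
#' For every membrane point of every organelle, the nearest Euclidean
#' distance to the membrane of any *different* organelle. Computed per
#' organelle by a distance transform of the union of all other membranes,
#' evaluated at the organelle's own membrane voxels (exact at voxel
#' centers).
#'
#' @param scene a [tomogram_scene()] with at least two organelles.
#' @return data.frame with `organelle`, `distance_nm`.
#' @export
inter_membrane_distances <- function(scene) {
  ids <- names(scene$membrane_points)
  if (length(ids) < 2)
    .stopf("inter-membrane analysis undefined with fewer than 2 organelles",
           class = "fibrilstats_error")
  d <- dim(scene$label_volume)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    other <- .membrane_mask(scene, exclude = ids[k])
    sq <- .edt3d_sq(as.logical(other), d)
    field <- array(sqrt(sq) * scene$voxel_size, dim = d)
    m <- scene$membrane_points[[ids[k]]]
    ijk <- round(m / scene$voxel_size) + 1L
    for (j in 1:3) ijk[, j] <- pmin(pmax(ijk[, j], 1L), d[j])
    out[[k]] <- data.frame(organelle = ids[k],
                           distance_nm = field[ijk])
  }
  do.call(rbind, out)
}

#' Bin a distance sample into a normalized profile
#'
#' Fixed-width histogram whose frequencies sum to 1. Distances above the
#' last edge are clamped into the final bin (and counted in
#' `n_overflow`).
#'
#' @param distances numeric vector (nm).
#' @param bin_width bin width in nm.
#' @param max_nm upper edge in nm.
#' @param source `"experimental"` or `"simulated"`.
#' @param tomogram optional tomogram id.
#' @return object of class `distance_profile`: `bin_edges`, `freq`,
#'   `sample_count`, `n_overflow`, `source`, `tomogram`.
#' @export
distance_profile <- function(distances, bin_width = 2, max_nm = 200,
                             source = c("experimental", "simulated"),
                             tomogram = NA_character_) {
  source <- match.arg(source)
  edges <- seq(0, max_nm, by = bin_width)
  nb <- length(edges) - 1L
  idx <- findInterval(distances, edges, rightmost.closed = TRUE)
  n_overflow <- sum(idx > nb)
  idx <- pmin(pmax(idx, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  n <- length(distances)
  structure(list(bin_edges = edges,
                 freq = if (n > 0) counts / n else rep(0, nb),
                 sample_count = n, n_overflow = n_overflow,
                 source = source, tomogram = tomogram),
            class = "distance_profile")
}

#' Median and 5-95% envelope of a set of distance profiles
#'
#' @param profiles list of [distance_profile()] with identical bin edges.
#' @return object of class `band_summary`: `bin_edges`, `median`, `p05`,
#'   `p95`, `n_curves`.
#' @export
band <- function(profiles) {
  if (!length(profiles)) .stopf("no profiles")
  edges <- profiles[[1]]$bin_edges
  for (p in profiles)
    if (!isTRUE(all.equal(p$bin_edges, edges)))
      .stopf("profiles have mismatched bin edges")
  M <- vapply(profiles, function(p) p$freq, numeric(length(edges) - 1L))
  M <- matrix(M, nrow = length(edges) - 1L)
  structure(list(bin_edges = edges,
                 median = apply(M, 1, median),
                 p05 = apply(M, 1, quantile, probs = 0.05, names = FALSE),
                 p95 = apply(M, 1, quantile, probs = 0.95, names = FALSE),
                 n_curves = length(profiles)),
            class = "band_summary")
}

#' Two-sample Kolmogorov-Smirnov comparison of close distances
#'
#' Truncates both samples to `[0, cutoff]` and runs a two-sample,
#' two-tailed KS test (asymptotic p value). Counts of truncated-away
#' values are returned.
#'
#' @param sample_a,sample_b numeric distance samples (nm).
#' @param cutoff truncation cutoff in nm (default 20, the close-contact
#'   zone).
#' @return object of class `ks_result`: `D`, `p`, `cutoff_nm`, `n_a`,
#'   `n_b`, `n_dropped_a`, `n_dropped_b`.
#' @export
ks_compare <- function(sample_a, sample_b,
                       cutoff = .default_contact_cutoff_nm) {
  a <- sample_a[sample_a >= 0 & sample_a <= cutoff]
  b <- sample_b[sample_b >= 0 & sample_b <= cutoff]
  if (!length(a) || !length(b))
    .stopf("no mass below cutoff %g nm", cutoff,
           class = "fibrilstats_error")
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided",
                                 exact = FALSE))
  structure(list(D = unname(kt$statistic), p = kt$p.value,
                 cutoff_nm = cutoff, n_a = length(a), n_b = length(b),
                 n_dropped_a = length(sample_a) - length(a),
                 n_dropped_b = length(sample_b) - length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("ks_result: D = %.3f, p = %.3g (cutoff %g nm; n = %d vs %d)\n",
              x$D, x$p, x$cutoff_nm, x$n_a, x$n_b))
  invisible(x)
}
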