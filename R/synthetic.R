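#' Generate a discrete worm-like-chain fibril
#'
#' Discrete 3D worm-like chain: starting from a uniformly random initial
#' tangent, each step deflects the tangent by a polar angle with uniform
#' azimuth. The polar deflection follows a von Mises-Fisher distribution
#' whose concentration is chosen so that the per-step mean cosine is
#' *exactly* `exp(-step / L_p)`; because azimuthally symmetric deflections
#' compound multiplicatively in their mean cosine, the ensemble tangent
#' correlation decays as `exp(-l / L_p)` exactly at every multiple of
#' `step` (the Gaussian small-angle sampler has the same limit but carries
#' an O((step/L_p)^2) stiffness bias). Consumes the current RNG state;
#' seed with [set.seed()] for reproducibility.
#'
#' @param L_p target persistence length (nm).
#' @param length target arc length (nm, >= 2 * step); realized length is
#'   `round(length / step) * step`.
#' @param step segment length (nm); must satisfy `step <= L_p / 10`.
#' @param start 3-vector starting point (nm).
#' @param id,radius passed to [fibril()].
#' @return a [fibril()] with uniformly spaced points.
#' @export
#' @examples
#' set.seed(1)
#' f <- generate_wlc_fibril(L_p = 1000, length = 250, step = 5)
#' fibril_length(f)
generate_wlc_fibril <- function(L_p, length, step, start = c(0, 0, 0),
                                id = "wlc", radius = .default_fibril_radius_nm) {
  if (step > L_p / 10)
    .stopf("step %g nm too coarse for L_p %g nm (need step <= L_p/10)",
           step, L_p, class = "fibrilstats_error")
  if (length < 2 * step) .stopf("length must be >= 2 * step")
  n_steps <- max(2L, as.integer(round(length / step)))
  t <- rnorm(3); t <- t / sqrt(sum(t^2))
  kappa <- .vmf_kappa(exp(-step / L_p))
  pts <- matrix(0, nrow = n_steps + 1L, ncol = 3)
  pts[1, ] <- start
  for (i in seq_len(n_steps)) {
    # orthonormal transverse frame around the current tangent
    ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n1 <- ref - sum(ref * t) * t
    n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(t[2] * n1[3] - t[3] * n1[2],
            t[3] * n1[1] - t[1] * n1[3],
            t[1] * n1[2] - t[2] * n1[1])
    w <- .vmf_cos(kappa)
    phi <- runif(1, 0, 2 * pi)
    s <- sqrt(max(0, 1 - w^2))
    t <- w * t + s * (cos(phi) * n1 + sin(phi) * n2)
    t <- t / sqrt(sum(t^2))
    pts[i + 1L, ] <- pts[i, ] + step * t
  }
  fibril(pts, id = id, radius = radius)
}

# concentration of a von Mises-Fisher polar deflection with mean cosine m:
# solves the Langevin function coth(k) - 1/k = m
.vmf_kappa <- function(m) {
  stopifnot(m > 0, m < 1)
  if (m > 0.95) return(1 / (1 - m))        # coth(k) == 1 in double precision
  stats::uniroot(function(k) 1 / tanh(k) - 1 / k - m,
                 lower = 1e-8, upper = 1e3, tol = 1e-12)$root
}

# polar cosine sample of vMF(kappa) about the pole (inverse-CDF form)
.vmf_cos <- function(kappa) {
  u <- runif(1)
  if (kappa > 350) return(min(1, 1 + log(u) / kappa))
  1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
}

#' Specification of a synthetic tomogram scene
#'
#' The stated world of the synthetic generator: a thin lamella (default
#' 400 x 400 x 150 nm at 5 nm voxels) containing non-overlapping voxelized
#' organelles and worm-like-chain fibrils with a log-normal length
#' distribution (mean 250 nm, truncated at the 100 nm tracing minimum).
#'
#' @param extent_nm physical X/Y/Z extents (nm).
#' @param voxel_size nm per voxel (isotropic).
#' @param lamella_thickness nm (defaults to the Z extent).
#' @param organelles list of per-organelle specs, each a list with `shape`
#'   (`"sphere"`, `"ellipsoid"`, `"tube"`) and size parameters in nm
#'   (`radius`; `semi_axes` (3-vector) for ellipsoids; `radius` +
#'   `half_length` for tubes).
#' @param placement `"uniform"` or `"clustered"`.
#' @param cluster_spacing_nm maximum planted surface gap when clustered.
#' @param n_fibrils number of fibrils.
#' @param L_p target persistence length (nm).
#' @param mean_length_nm mean of the log-normal length distribution.
#' @param sdlog_length log-scale sd of the length distribution.
#' @param min_length_nm truncation minimum (nm).
#' @param step_nm worm-like-chain step (nm).
#' @param attraction_strength membrane attraction in `[0, 1]` (0 = none).
#' @param attraction_range_nm range of the planted attraction (nm).
#' @param rng_seed master seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(extent_nm = c(400, 400, 150), voxel_size = 5,
                       lamella_thickness = extent_nm[3],
                       organelles = replicate(4, list(shape = "sphere",
                                                      radius = 30),
                                              simplify = FALSE),
                       placement = c("uniform", "clustered"),
                       cluster_spacing_nm = 10,
                       n_fibrils = 40, L_p = 1000,
                       mean_length_nm = 250, sdlog_length = 0.4,
                       min_length_nm = .default_min_fibril_length_nm,
                       step_nm = 5,
                       attraction_strength = 0, attraction_range_nm = 20,
                       rng_seed = 1L) {
  placement <- match.arg(placement)
  if (attraction_strength < 0 || attraction_strength > 1)
    .stopf("attraction_strength must be in [0, 1]")
  if (attraction_strength > 0 && attraction_range_nm <= 0)
    .stopf("attraction_range_nm must be positive when attraction is on")
  structure(list(extent_nm = extent_nm, voxel_size = voxel_size,
                 lamella_thickness = lamella_thickness,
                 organelles = organelles, placement = placement,
                 cluster_spacing_nm = cluster_spacing_nm,
                 n_fibrils = n_fibrils, L_p = L_p,
                 mean_length_nm = mean_length_nm,
                 sdlog_length = sdlog_length,
                 min_length_nm = min_length_nm, step_nm = step_nm,
                 attraction_strength = attraction_strength,
                 attraction_range_nm = attraction_range_nm,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# voxel linear indices covered by an organelle; axis-aligned ellipsoids,
# spheres, and capsule-shaped tubes along a given unit axis
.voxelize_organelle <- function(org, center, dims, vs, axis = NULL) {
  eff <- .organelle_extent(org)
  rng <- lapply(1:3, function(j) {
    lo <- max(1L, floor((center[j] - eff) / vs) + 1L)
    hi <- min(dims[j], ceiling((center[j] + eff) / vs) + 1L)
    lo:hi
  })
  gx <- (rng[[1]] - 1) * vs; gy <- (rng[[2]] - 1) * vs; gz <- (rng[[3]] - 1) * vs
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  px <- rep(gx, times = ny * nz) - center[1]
  py <- rep(rep(gy, each = nx), times = nz) - center[2]
  pz <- rep(gz, each = nx * ny) - center[3]
  inside <- switch(org$shape,
    sphere = px^2 + py^2 + pz^2 <= org$radius^2,
    ellipsoid = (px / org$semi_axes[1])^2 + (py / org$semi_axes[2])^2 +
      (pz / org$semi_axes[3])^2 <= 1,
    tube = {
      proj <- px * axis[1] + py * axis[2] + pz * axis[3]
      proj <- pmin(pmax(proj, -org$half_length), org$half_length)
      (px - proj * axis[1])^2 + (py - proj * axis[2])^2 +
        (pz - proj * axis[3])^2 <= org$radius^2
    },
    .stopf("unknown organelle shape '%s'", org$shape))
  ii <- rep(rng[[1]], times = ny * nz)
  jj <- rep(rep(rng[[2]], each = nx), times = nz)
  kk <- rep(rng[[3]], each = nx * ny)
  (kk[inside] - 1L) * dims[1] * dims[2] + (jj[inside] - 1L) * dims[1] +
    ii[inside]
}

.organelle_extent <- function(org) {
  switch(org$shape,
         sphere = org$radius,
         ellipsoid = max(org$semi_axes),
         tube = org$half_length + org$radius,
         .stopf("unknown organelle shape '%s'", org$shape))
}

#' Generate a synthetic scene with ground truth
#'
#' Voxelizes the organelles of a [scene_spec()] into a label volume
#' without overlap (rejection sampling; clustered placement draws each
#' subsequent center so the surface gap to an already placed organelle is
#' below `cluster_spacing_nm`), then places worm-like-chain fibrils by
#' rigid motion, rejecting placements that enter a lumen. With
#' `attraction_strength > 0`, placements whose minimum membrane distance
#' exceeds `attraction_range_nm` are only accepted with probability
#' `1 - attraction_strength`, planting an enrichment of close
#' fibril-membrane contacts.
#'
#' @param spec a [scene_spec()].
#' @param max_tries rejection budget per object.
#' @return list with `scene` (a [tomogram_scene()]), `fibrils` (list of
#'   [fibril()]), and `truth` (planted parameters and per-object records).
#' @export
generate_scene <- function(spec, max_tries = 2000) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(derive_seed(spec$rng_seed, 1))
  vs <- spec$voxel_size
  dims <- pmax(2L, as.integer(round(spec$extent_nm / vs)))
  lab <- array(0L, dims)
  centers <- list()
  eff_radii <- numeric(0)

  for (k in seq_along(spec$organelles)) {
    org <- spec$organelles[[k]]
    eff <- .organelle_extent(org)
    lo <- eff + vs; hi <- (dims - 1) * vs - eff - vs
    if (any(hi < lo))
      .stopf("organelle %d does not fit in the scene", k)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (spec$placement == "clustered" && k > 1) {
        ref <- sample.int(k - 1, 1)
        gap <- runif(1, vs, max(vs, spec$cluster_spacing_nm - vs))
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        center <- centers[[ref]] + dir * (eff_radii[ref] + eff + gap)
        if (any(center < lo) || any(center > hi)) next
      } else {
        center <- runif(3, lo, hi)
      }
      axis <- NULL
      if (org$shape == "tube") {
        axis <- rnorm(3); axis[3] <- axis[3] * 0.2  # mostly in-plane
        axis <- axis / sqrt(sum(axis^2))
      }
      idx <- .voxelize_organelle(org, center, dims, vs, axis)
      if (!length(idx) || any(lab[idx] > 0L)) next
      lab[idx] <- k
      centers[[k]] <- center
      eff_radii[k] <- eff
      placed <- TRUE
      break
    }
    if (!placed)
      .stopf("organelle %d: rejection budget exhausted (packing fraction %.2f)",
             k, sum(lab > 0L) / length(lab), class = "fibrilstats_error")
  }

  scene <- tomogram_scene(lab, voxel_size = vs,
                          lamella_thickness = min(spec$lamella_thickness,
                                                  dims[3] * vs))
  field <- NULL
  if (length(scene$membrane_points) && spec$attraction_strength > 0)
    field <- membrane_distance_field(scene)

  fibrils <- vector("list", spec$n_fibrils)
  if (spec$n_fibrils > 0) {
    mu <- log(spec$mean_length_nm) - spec$sdlog_length^2 / 2
    # upper truncation: a fibril must fit in the box under some rotation;
    # mirrors the field-of-view clipping of real tomogram tracing
    len_max <- 0.8 * sqrt(sum(spec$extent_nm^2))
    if (len_max <= spec$min_length_nm)
      .stopf("scene too small for the minimum fibril length")
    for (i in seq_len(spec$n_fibrils)) {
      repeat {
        len <- exp(rnorm(1, mu, spec$sdlog_length))
        if (len >= spec$min_length_nm && len <= len_max) break
      }
      base <- generate_wlc_fibril(spec$L_p, len, spec$step_nm, id = i)
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- randomize_fibrils(scene, list(base), max_retries = max_tries)
        f <- cand[[1]]
        if (!is.null(field)) {
          dmin <- min(.interp_trilinear(field$field, vs, f$points))
          if (dmin > spec$attraction_range_nm &&
              runif(1) > 1 - spec$attraction_strength) next
        }
        fibrils[[i]] <- f
        placed <- TRUE
        break
      }
      if (!placed)
        .stopf("fibril %d: placement budget exhausted", i,
               class = "fibrilstats_error")
    }
  }

  truth <- list(spec = unclass(spec), organelle_centers = centers,
                organelle_extents = eff_radii,
                fibril_lengths = vapply(fibrils, fibril_length, numeric(1)))
  list(scene = scene, fibrils = fibrils, truth = truth)
}

#' Generate 1D gold-label positions along a fibril axis
#'
#' Labels every `k`-th beta-strand: positions `i * k * spacing` plus
#' Gaussian jitter, in Angstrom. Successive differences have mean
#' `k * spacing`.
#'
#' @param k strands per label (>= 1).
#' @param spacing beta-strand repeat (Angstrom; default 4.8).
#' @param jitter Gaussian jitter sd (Angstrom); must stay below
#'   `k * spacing / 2` so label ordering is preserved.
#' @param n_labels number of labels.
#' @return numeric vector of positions (Angstrom).
#' @export
generate_gold_fixture <- function(k, spacing = 4.8, jitter = 0, n_labels = 20) {
  if (k < 1 || spacing <= 0) .stopf("need k >= 1 and spacing > 0")
  if (jitter >= k * spacing / 2)
    .stopf("jitter %g breaks label ordering (must be < k*spacing/2 = %g)",
           jitter, k * spacing / 2)
  (seq_len(n_labels) - 1) * k * spacing +
    if (jitter > 0) rnorm(n_labels, 0, jitter) else 0
}

#' Write a generated scene to disk in exchange formats
#'
#' MRC label volume, CSV and VTK fibril polylines, JSON ground truth.
#'
#' @param gen result of [generate_scene()].
#' @param dir output directory (created).
#' @param basename file stem.
#' @return named character vector of paths, invisibly.
#' @export
write_scene <- function(gen, dir, basename = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mrc = file.path(dir, paste0(basename, "_labels.mrc")),
    csv = file.path(dir, paste0(basename, "_fibrils.csv")),
    vtk = file.path(dir, paste0(basename, "_fibrils.vtk")),
    truth = file.path(dir, paste0(basename, "_truth.json")))
  write_label_volume(gen$scene, paths["mrc"])
  write_fibrils_csv(gen$fibrils, paths["csv"])
  write_fibrils_vtk(gen$fibrils, paths["vtk"])
  jsonlite::write_json(gen$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(paths)
}
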