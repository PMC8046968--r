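# Uniform random rotation matrix (Haar measure on SO(3)) via a uniform
# unit quaternion; "in_plane" restricts to rotations about the Z axis.
.random_rotation <- function(mode = "full") {
  if (mode == "in_plane") {
    a <- runif(1, 0, 2 * pi)
    return(rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1)))
  }
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Randomize fibril placements by rigid motion
#'
#' Each fibril independently receives a uniform random rotation about its
#' centroid (uniform over 3D rotations, or about Z only with
#' `rotations = "in_plane"`) and a uniform random translation such that all
#' points stay inside the scene bounds. Placements with any point inside an
#' organelle lumen (label > 0) are rejected and redrawn. Shape and length
#' are preserved exactly.
#'
#' @param scene a [tomogram_scene()].
#' @param fibrils list of [fibril()].
#' @param rotations `"full"` or `"in_plane"`.
#' @param max_retries retry budget per fibril (default 1000).
#' @return list of repositioned [fibril()]; attribute `retries` gives the
#'   per-fibril rejection counts.
#' @export
randomize_fibrils <- function(scene, fibrils, rotations = "full",
                              max_retries = 1000) {
  stopifnot(inherits(scene, "tomogram_scene"))
  rotations <- match.arg(rotations, c("full", "in_plane"))
  lo <- scene$bounds["lower", ]; hi <- scene$bounds["upper", ]
  lab <- scene$label_volume
  d <- dim(lab)
  vs <- scene$voxel_size
  out <- vector("list", length(fibrils))
  retries <- integer(length(fibrils))
  nvox <- as.integer(prod(d))
  strides <- c(1L, d[1], d[1] * d[2])
  for (k in seq_along(fibrils)) {
    f <- fibrils[[k]]
    np <- nrow(f$points)
    ctr <- colMeans(f$points)
    rel0 <- f$points - matrix(ctr, np, 3, byrow = TRUE)
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      R <- .random_rotation(rotations)
      rel <- rel0 %*% R          # R orthogonal: right-multiplication rotates
      rmin <- c(min(rel[, 1]), min(rel[, 2]), min(rel[, 3]))
      rmax <- c(max(rel[, 1]), max(rel[, 2]), max(rel[, 3]))
      if (any(hi - rmax < lo - rmin)) { retries[k] <- retries[k] + 1L; next }
      cen <- runif(3, lo - rmin, hi - rmax)
      pts <- rel + matrix(cen, np, 3, byrow = TRUE)
      ijk <- round(pts / vs)
      for (j in 1:3) ijk[, j] <- pmin.int(pmax.int(ijk[, j], 0), d[j] - 1L)
      lin <- 1L + as.integer(ijk %*% strides)
      if (any(lab[lin] > 0L)) { retries[k] <- retries[k] + 1L; next }
      out[[k]] <- structure(list(points = `colnames<-`(pts, c("x", "y", "z")),
                                 id = f$id, radius = f$radius),
                            class = "fibril")
      placed <- TRUE
      break
    }
    if (!placed) {
      crowd <- sum(lab > 0L) / length(lab)
      .stopf(paste0("could not place fibril %s in %d tries ",
                    "(lumen fraction %.2f); scene too crowded or fibril too ",
                    "large"), f$id, max_retries, crowd,
             class = "fibrilstats_error")
    }
  }
  structure(out, retries = retries)
}

#' Monte-Carlo null ensemble of fibril-membrane distance profiles
#'
#' Repeats [randomize_fibrils()] `n_simulations` times; for each
#' simulation, fibril-membrane distances are recomputed against the fixed
#' membrane distance field and binned into a [distance_profile()]. Each
#' simulation runs on its own RNG substream derived from `(seed, sim)` via
#' [derive_seed()], so the ensemble is reproducible and order-independent.
#'
#' @param scene a [tomogram_scene()].
#' @param fibrils list of [fibril()] (experimental placements).
#' @param n_simulations number of randomizations (default 200).
#' @param seed master seed.
#' @param field optional precomputed [membrane_distance_field()].
#' @param bin_width,max_nm histogram parameters (nm).
#' @param step fibril resampling step (nm; default voxel size).
#' @param rotations `"full"` or `"in_plane"`.
#' @param max_retries per-fibril retry budget.
#' @return object of class `null_ensemble`: list of `profiles`, matrix
#'   `distances` is not stored (memory); fields `n_simulations`, `seed`,
#'   `retries` (total per simulation), `samples` (list of per-simulation
#'   distance vectors), `per_fibril_min` (matrix n_fibrils x n_simulations).
#' @export
null_ensemble <- function(scene, fibrils,
                          n_simulations = .default_n_simulations,
                          seed = 1L, field = NULL,
                          bin_width = 2, max_nm = 200,
                          step = scene$voxel_size,
                          rotations = "full", max_retries = 1000) {
  if (n_simulations < 1) .stopf("n_simulations must be >= 1")
  if (is.null(field)) field <- membrane_distance_field(scene)
  # resample once; rigid motion commutes with arc-length resampling
  fib_rs <- lapply(fibrils, function(f)
    suppressWarnings(resample_polyline(f, step)))
  profiles <- vector("list", n_simulations)
  samples <- vector("list", n_simulations)
  pf_min <- matrix(NA_real_, nrow = length(fibrils), ncol = n_simulations)
  retries <- integer(n_simulations)
  for (s in seq_len(n_simulations)) {
    set.seed(derive_seed(seed, s))
    rf <- randomize_fibrils(scene, fib_rs, rotations = rotations,
                            max_retries = max_retries)
    retries[s] <- sum(attr(rf, "retries"))
    dd <- fibril_membrane_distances(rf, field, resample = FALSE)
    profiles[[s]] <- distance_profile(dd$distance_nm, bin_width, max_nm,
                                      source = "simulated")
    samples[[s]] <- dd$distance_nm
    if (length(fibrils))
      pf_min[, s] <- vapply(split(dd$distance_nm, factor(dd$fibril_id,
                              levels = unique(dd$fibril_id))),
                            min, numeric(1))
  }
  structure(list(profiles = profiles, samples = samples,
                 per_fibril_min = pf_min,
                 n_simulations = as.integer(n_simulations),
                 seed = as.integer(seed), retries = retries),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d simulations (seed %d), mean retries %.1f\n",
              x$n_simulations, x$seed, mean(x$retries)))
  invisible(x)
}

#' Fraction of a distance sample below a cutoff
#'
#' The "close-contact mass": the fraction of nearest distances below the
#' contact cutoff (20 nm by default). The scale on which the experimental
#' placements are compared against the null ensemble's 95th percentile.
#'
#' @param distances numeric vector (nm).
#' @param cutoff cutoff in nm.
#' @return fraction in `[0, 1]`.
#' @export
contact_mass <- function(distances, cutoff = .default_contact_cutoff_nm) {
  if (!length(distances)) return(NA_real_)
  mean(distances < cutoff)
}
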