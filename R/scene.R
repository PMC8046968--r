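#' Construct a tomogram scene
#'
#' A `tomogram_scene` is the geometric universe of one tomogram: an integer
#' label volume (0 = background/cytosol, k >= 1 = lumen of organelle k), an
#' isotropic voxel size in nm, per-organelle membrane point sets, and the
#' lamella thickness used for volume computations. World coordinates follow
#' the convention `world_nm = voxel_index * voxel_size` with 0-based indices,
#' i.e. voxel centers sit on a regular grid starting at the origin.
#'
#' @param label_volume 3D integer array; 0 background, k >= 1 organelle lumen.
#' @param voxel_size voxel edge in nm (isotropic, > 0).
#' @param membrane_points optional named list (names = organelle ids) of
#'   n x 3 matrices of membrane points in nm. When `NULL`, membranes are
#'   derived as the 26-connected boundary voxels of each lumen label, at
#'   voxel centers. An explicit membrane set takes precedence over the
#'   derived one.
#' @param lamella_thickness thickness of the imaged slab in nm; defaults to
#'   the full Z extent `dim[3] * voxel_size`. Must not exceed the Z extent.
#' @return object of class `tomogram_scene` with fields `label_volume`,
#'   `voxel_size`, `membrane_points`, `bounds` (2 x 3 matrix of voxel-center
#'   bounds in nm), `extent` (physical X/Y/Z extents, nm), and
#'   `lamella_thickness`.
#' @export
#' @examples
#' lab <- array(0L, c(10, 10, 10)); lab[4:6, 4:6, 4:6] <- 1L
#' sc <- tomogram_scene(lab, voxel_size = 2)
#' nrow(sc$membrane_points[["1"]])  # boundary voxels of the cube
tomogram_scene <- function(label_volume, voxel_size,
                           membrane_points = NULL,
                           lamella_thickness = NULL) {
  if (length(dim(label_volume)) != 3)
    .stopf("label_volume must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    .stopf("voxel_size must be a positive scalar (nm)",
           class = "fibrilstats_unit_error")
  storage.mode(label_volume) <- "integer"
  d <- dim(label_volume)
  extent <- d * voxel_size
  if (is.null(lamella_thickness)) lamella_thickness <- extent[3]
  if (lamella_thickness <= 0 || lamella_thickness > extent[3] + 1e-9)
    .stopf("lamella_thickness must lie in (0, Z extent = %g nm]", extent[3])

  if (is.null(membrane_points)) {
    membrane_points <- derive_membrane_points(label_volume, voxel_size)
  } else {
    membrane_points <- lapply(membrane_points, function(m) {
      m <- as.matrix(m)
      if (ncol(m) != 3) .stopf("membrane point sets must be n x 3 (nm)")
      m
    })
  }

  structure(list(
    label_volume = label_volume,
    voxel_size = voxel_size,
    membrane_points = membrane_points,
    bounds = rbind(lower = c(0, 0, 0), upper = (d - 1) * voxel_size),
    extent = extent,
    lamella_thickness = lamella_thickness
  ), class = "tomogram_scene")
}

#' @export
print.tomogram_scene <- function(x, ...) {
  d <- dim(x$label_volume)
  cat(sprintf("tomogram_scene: %d x %d x %d voxels @ %g nm (%g x %g x %g nm)\n",
              d[1], d[2], d[3], x$voxel_size,
              x$extent[1], x$extent[2], x$extent[3]))
  cat(sprintf("  organelles: %d; lamella thickness: %g nm\n",
              length(x$membrane_points), x$lamella_thickness))
  invisible(x)
}

#' Membrane point sets from a label volume
#'
#' Boundary voxels (26-connectivity) of each positive label, returned as
#' world coordinates of voxel centers in nm, one matrix per organelle id.
#'
#' @param label_volume 3D integer array.
#' @param voxel_size nm per voxel.
#' @return named list of n x 3 matrices.
#' @export
derive_membrane_points <- function(label_volume, voxel_size) {
  storage.mode(label_volume) <- "integer"
  d <- dim(label_volume)
  bmask <- .label_boundary(label_volume, d)
  idx <- which(array(bmask, d))
  if (length(idx) == 0) return(setNames(list(), character(0)))
  labs <- label_volume[idx]
  coords <- arrayInd(idx, d) - 1L
  out <- lapply(split(seq_along(idx), labs), function(rows) {
    m <- coords[rows, , drop = FALSE] * voxel_size
    colnames(m) <- c("x", "y", "z")
    m
  })
  out[order(as.integer(names(out)))]
}

#' Read a segmentation label volume into a scene
#'
#' Reads an MRC2014 file, converts the header voxel size from Angstrom to
#' nm, rounds data to integer labels, and derives membrane point sets as the
#' 26-connected boundary voxels of each lumen label.
#'
#' @param path MRC file path.
#' @param voxel_size_nm optional override of the header voxel size (nm);
#'   required when the header carries no positive voxel size.
#' @param lamella_thickness passed to [tomogram_scene()].
#' @param membrane_points optional explicit membrane point sets (take
#'   precedence over boundary-derived ones).
#' @return a [tomogram_scene()].
#' @export
read_label_volume <- function(path, voxel_size_nm = NULL,
                              lamella_thickness = NULL,
                              membrane_points = NULL) {
  m <- read_mrc(path)
  vs <- if (!is.null(voxel_size_nm)) voxel_size_nm else m$voxel_size_ang / 10
  if (is.na(vs) || !length(vs) || vs <= 0)
    .stopf("MRC header of %s has no positive voxel size; pass voxel_size_nm",
           path, class = "fibrilstats_unit_error")
  lab <- round(m$data)
  if (max(abs(m$data - lab)) > 1e-4)
    .stopf("%s does not contain integer-convertible label data", path,
           class = "fibrilstats_format_error")
  tomogram_scene(lab, voxel_size = vs, membrane_points = membrane_points,
                 lamella_thickness = lamella_thickness)
}

#' Write a scene's label volume as MRC2014
#'
#' @param scene a [tomogram_scene()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(scene, path) {
  write_mrc(scene$label_volume, path, voxel_size_ang = scene$voxel_size * 10)
}

#' Organelle ids present in a scene
#' @param scene a [tomogram_scene()].
#' @return integer vector of organelle ids.
#' @export
organelle_ids <- function(scene) {
  as.integer(names(scene$membrane_points))
}

#' Run configuration
#'
#' Bundles the tunable analysis parameters with provenance of the upstream
#' filament tracing (recorded, not interpreted). Defaults follow the
#' analysis conventions: 2 nm histogram bins over 0-200 nm, a 20 nm close
#' contact cutoff, 200 null simulations.
#'
#' @param bin_width_nm histogram bin width (nm).
#' @param hist_max_nm histogram upper edge (nm).
#' @param contact_cutoff_nm close-contact cutoff (nm); must be below
#'   `hist_max_nm`.
#' @param n_simulations number of rigid-motion null simulations.
#' @param resample_step_nm polyline resampling step for tangent estimation
#'   (nm).
#' @param min_fibril_length_nm minimum retained fibril length (nm).
#' @param fibril_radius_nm fibril radius for cylinder volumes / Young's
#'   modulus (nm).
#' @param temperature_K absolute temperature for the Young's modulus.
#' @param rotations `"full"` (uniform over 3D rotations) or `"in_plane"`
#'   (about Z only) for the null model.
#' @param rng_seed master seed.
#' @param provenance free-form list recording upstream tracing parameters.
#' @return object of class `run_config`.
#' @export
run_config <- function(bin_width_nm = 2,
                       hist_max_nm = 200,
                       contact_cutoff_nm = .default_contact_cutoff_nm,
                       n_simulations = .default_n_simulations,
                       resample_step_nm = 5,
                       min_fibril_length_nm = .default_min_fibril_length_nm,
                       fibril_radius_nm = .default_fibril_radius_nm,
                       temperature_K = .default_temperature_K,
                       rotations = c("full", "in_plane"),
                       rng_seed = 1L,
                       provenance = list(template_nm = c(10, 80),
                                         cone_nm = 50, cone_deg = 37,
                                         direction_coefficient = 0.3)) {
  rotations <- match.arg(rotations)
  vals <- c(bin_width_nm, hist_max_nm, contact_cutoff_nm, n_simulations,
            resample_step_nm, min_fibril_length_nm, fibril_radius_nm,
            temperature_K)
  if (any(!is.finite(vals)) || any(vals <= 0))
    .stopf("all run_config numeric parameters must be positive")
  if (contact_cutoff_nm >= hist_max_nm)
    .stopf("contact_cutoff_nm must be below the histogram range")
  cfg <- list(bin_width_nm = bin_width_nm, hist_max_nm = hist_max_nm,
              contact_cutoff_nm = contact_cutoff_nm,
              n_simulations = as.integer(n_simulations),
              resample_step_nm = resample_step_nm,
              min_fibril_length_nm = min_fibril_length_nm,
              fibril_radius_nm = fibril_radius_nm,
              temperature_K = temperature_K,
              rotations = rotations,
              rng_seed = as.integer(rng_seed),
              provenance = provenance)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with any subset of [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(x), names(formals(run_config)))
  do.call(run_config, x[keep])
}
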