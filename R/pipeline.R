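#' One-way ANOVA of per-tomogram fibril densities
#'
#' Standard one-way ANOVA of density values grouped by condition, with
#' pairwise Welch t-tests reported alongside (labelled as such; the ANOVA
#' is the primary test).
#'
#' @param densities data.frame with columns `condition` and `density`
#'   (one row per tomogram).
#' @return object of class `anova_result`: `F`, `p`, `df`, `group_means`,
#'   `pairwise` (data.frame of Welch t-tests), `table`.
#' @export
anova_densities <- function(densities) {
  stopifnot(is.data.frame(densities),
            all(c("condition", "density") %in% names(densities)))
  densities$condition <- factor(densities$condition)
  tab_n <- table(densities$condition)
  if (length(tab_n) < 2 || any(tab_n < 2))
    .stopf("need >= 2 groups with >= 2 tomograms each",
           class = "fibrilstats_error")
  if (all(tapply(densities$density, densities$condition, stats::var) == 0) &&
      stats::var(densities$density) == 0)
    .stopf("all groups are identical constants; F is undefined",
           class = "fibrilstats_error")
  fit <- aov(density ~ condition, data = densities)
  at <- anova(fit)
  lv <- levels(densities$condition)
  pairs <- utils::combn(lv, 2)
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ], p_welch = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    xa <- densities$density[densities$condition == pairs[1, i]]
    xb <- densities$density[densities$condition == pairs[2, i]]
    pw$p_welch[i] <- tryCatch(t.test(xa, xb)$p.value,
                              error = function(e) NA_real_)
  }
  structure(list(F = at[1, "F value"], p = at[1, "Pr(>F)"],
                 df = unname(at[["Df"]]),
                 group_means = c(tapply(densities$density,
                                        densities$condition, mean)),
                 pairwise = pw, table = at),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("anova_result: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

.load_tomogram <- function(tomo, config) {
  scene <- tomo$scene
  fibrils <- tomo$fibrils
  if (is.character(scene))
    scene <- read_label_volume(scene,
                               voxel_size_nm = tomo$voxel_size_nm,
                               lamella_thickness = tomo$lamella_thickness)
  if (is.character(fibrils))
    fibrils <- read_fibrils(fibrils,
                            min_length = config$min_fibril_length_nm,
                            radius = config$fibril_radius_nm)
  list(scene = scene, fibrils = fibrils,
       id = if (!is.null(tomo$id)) tomo$id else NA_character_)
}

#' Run the full analysis pipeline over conditions of tomograms
#'
#' Executes, per condition: descriptive metrics (fibril lengths, cytosolic
#' density), pooled persistence-length estimation, fibril-membrane and
#' inter-membrane distance profiles with 5-95% bands, the rigid-motion
#' null ensemble, and the close-contact KS comparison; then the
#' between-condition density ANOVA. Scenes without organelles skip the
#' distance stages (marked "not applicable"). All randomness derives from
#' `config$rng_seed` via per-tomogram substreams, so reruns with an
#' identical configuration reproduce outputs exactly.
#'
#' @param config a [run_config()].
#' @param inputs named list (one entry per condition) of lists of
#'   tomograms; each tomogram is a list with `scene` (a
#'   [tomogram_scene()] or an MRC path), `fibrils` (a list of [fibril()]
#'   or a CSV/VTK path), and optionally `id`, `voxel_size_nm`,
#'   `lamella_thickness`.
#' @param out_dir optional output directory; when given, all tables and a
#'   JSON log (with the configuration hash and seed) are written there.
#' @param stages subset of `c("metrics", "persistence", "distances",
#'   "null")` to run (metrics always run).
#' @return named list of per-condition summaries (class
#'   `condition_summary`) with attribute `anova` (the density ANOVA, when
#'   >= 2 eligible conditions) and `config_hash`.
#' @export
run_pipeline <- function(config, inputs, out_dir = NULL,
                         stages = c("metrics", "persistence", "distances",
                                    "null")) {
  stopifnot(inherits(config, "run_config"), length(inputs) >= 1)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    .stopf("inputs must be a named list of conditions")
  hash <- .config_hash(unclass(config))
  log <- list()
  note <- function(stage, cond, tomo, msg)
    log[[length(log) + 1]] <<- list(stage = stage, condition = cond,
                                    tomogram = tomo, message = msg)

  summaries <- list()
  for (cond in names(inputs)) {
    tomos <- lapply(inputs[[cond]], .load_tomogram, config = config)
    for (i in seq_along(tomos))
      if (is.na(tomos[[i]]$id)) tomos[[i]]$id <- sprintf("%s_%d", cond, i)

    dens <- list(); lengths <- list()
    fm_profiles <- list(); im_profiles <- list()
    nulls <- list(); exp_min <- list(); null_min <- list()
    all_fibrils <- list()
    for (i in seq_along(tomos)) {
      tm <- tomos[[i]]
      stage <- "metrics"
      res <- tryCatch({
        dens[[i]] <- cytosolic_fibril_density(tm$scene, tm$fibrils,
                                              tomogram = tm$id)
        lengths[[i]] <- vapply(tm$fibrils, fibril_length, numeric(1))
        all_fibrils <- c(all_fibrils, tm$fibrils)

        has_org <- length(tm$scene$membrane_points) > 0
        if ("distances" %in% stages && has_org && length(tm$fibrils)) {
          stage <- "distances"
          fld <- membrane_distance_field(tm$scene)
          dd <- fibril_membrane_distances(tm$fibrils, fld)
          fm_profiles[[tm$id]] <- distance_profile(
            dd$distance_nm, config$bin_width_nm, config$hist_max_nm,
            source = "experimental", tomogram = tm$id)
          exp_min[[tm$id]] <- vapply(
            split(dd$distance_nm, factor(dd$fibril_id,
                                         levels = unique(dd$fibril_id))),
            min, numeric(1))
          if (length(tm$scene$membrane_points) >= 2)
            im_profiles[[tm$id]] <- distance_profile(
              inter_membrane_distances(tm$scene)$distance_nm,
              config$bin_width_nm, config$hist_max_nm,
              source = "experimental", tomogram = tm$id)
          if ("null" %in% stages) {
            stage <- "null"
            ne <- null_ensemble(
              tm$scene, tm$fibrils,
              n_simulations = config$n_simulations,
              seed = derive_seed(config$rng_seed, match(cond, names(inputs)), i),
              field = fld, bin_width = config$bin_width_nm,
              max_nm = config$hist_max_nm,
              step = config$resample_step_nm,
              rotations = config$rotations)
            nulls[[tm$id]] <- ne
            null_min[[tm$id]] <- as.numeric(ne$per_fibril_min)
          }
        } else if (!has_org) {
          note("distances", cond, tm$id, "not applicable: no organelles")
        }
        NULL
      }, fibrilstats_error = function(e)
        .stopf("stage '%s' failed for tomogram %s: %s", stage, tm$id,
               conditionMessage(e)))
    }

    pers <- NULL
    if ("persistence" %in% stages && length(all_fibrils)) {
      pers <- tryCatch({
        max_sep <- min(500, max(vapply(all_fibrils, fibril_length,
                                       numeric(1))))
        curve <- tangent_correlation(all_fibrils,
                                     step = config$resample_step_nm,
                                     max_sep = max_sep)
        fit_persistence_length(curve,
                               radius_nm = config$fibril_radius_nm,
                               temperature_K = config$temperature_K)
      }, fibrilstats_estimation_error = function(e) {
        note("persistence", cond, NA, conditionMessage(e)); NULL
      })
    }

    ks_fm <- NULL
    if (length(exp_min) && length(null_min)) {
      ks_fm <- tryCatch(
        ks_compare(unlist(exp_min), unlist(null_min),
                   cutoff = config$contact_cutoff_nm),
        fibrilstats_error = function(e) {
          note("ks", cond, NA, conditionMessage(e)); NULL
        })
    }

    summaries[[cond]] <- structure(list(
      condition = cond,
      densities = dens,
      lengths = unlist(lengths),
      length_hist = length_histogram(all_fibrils),
      persistence = pers,
      fm_profiles = fm_profiles,
      fm_band = if (length(fm_profiles)) band(fm_profiles) else NULL,
      im_profiles = im_profiles,
      im_band = if (length(im_profiles)) band(im_profiles) else NULL,
      nulls = nulls,
      null_band = if (length(nulls)) band(unlist(lapply(nulls,
        function(n) n$profiles), recursive = FALSE)) else NULL,
      ks_fibril_membrane = ks_fm
    ), class = "condition_summary")
  }

  an <- NULL
  dens_df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(condition = s$condition,
               density = vapply(s$densities, function(d) d$density,
                                numeric(1)))))
  if (length(unique(dens_df$condition)) >= 2 &&
      all(table(dens_df$condition) >= 2))
    an <- anova_densities(dens_df)

  attr(summaries, "anova") <- an
  attr(summaries, "config_hash") <- hash
  attr(summaries, "log") <- log
  if (!is.null(out_dir)) .write_summaries(summaries, config, out_dir)
  summaries
}

.write_summaries <- function(summaries, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config = unclass(config),
               config_hash = attr(summaries, "config_hash"),
               rng_seed = config$rng_seed,
               multiple_testing_correction = "none")
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (cond in names(summaries)) {
    s <- summaries[[cond]]
    stem <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", cond))
    write.csv(data.frame(length_nm = s$lengths),
              paste0(stem, "_lengths.csv"), row.names = FALSE)
    write.csv(do.call(rbind, lapply(s$densities, function(d)
      data.frame(tomogram = d$tomogram,
                 cytosolic_volume_nm3 = d$cytosolic_volume_nm3,
                 fibril_volume_nm3 = d$fibril_volume_nm3,
                 density = d$density))),
      paste0(stem, "_densities.csv"), row.names = FALSE)
    write.csv(s$length_hist, paste0(stem, "_length_hist.csv"),
              row.names = FALSE)
    if (!is.null(s$persistence))
      jsonlite::write_json(unclass(s$persistence),
                           paste0(stem, "_persistence.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(s$fm_band)) {
      b <- s$fm_band
      write.csv(data.frame(bin_left = b$bin_edges[-length(b$bin_edges)],
                           bin_right = b$bin_edges[-1],
                           median = b$median, p05 = b$p05, p95 = b$p95),
                paste0(stem, "_fm_band.csv"), row.names = FALSE)
    }
    if (!is.null(s$ks_fibril_membrane))
      jsonlite::write_json(unclass(s$ks_fibril_membrane),
                           paste0(stem, "_ks.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  an <- attr(summaries, "anova")
  if (!is.null(an))
    jsonlite::write_json(list(F = an$F, p = an$p, df = an$df,
                              group_means = as.list(an$group_means),
                              pairwise = an$pairwise),
                         file.path(out_dir, "anova_densities.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  lg <- attr(summaries, "log")
  writeLines(vapply(lg, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE, null = "null"), character(1)),
    file.path(out_dir, "log.jsonl"))
  invisible(out_dir)
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("condition_summary '%s': %d tomograms, %d fibrils\n",
              x$condition, length(x$densities), length(x$lengths)))
  if (length(x$lengths))
    cat(sprintf("  mean length %.1f nm; mean density %.3e\n",
                mean(x$lengths),
                mean(vapply(x$densities, function(d) d$density, numeric(1)))))
  if (!is.null(x$persistence))
    cat(sprintf("  L_p = %.4g nm, E = %.3g Pa\n",
                x$persistence$L_p_nm, x$persistence$E_Pa))
  if (!is.null(x$ks_fibril_membrane))
    cat(sprintf("  fibril-membrane KS: D = %.3f, p = %.3g\n",
                x$ks_fibril_membrane$D, x$ks_fibril_membrane$p))
  invisible(x)
}
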