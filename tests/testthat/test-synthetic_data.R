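test_that("WLC generator: rigid limit, determinism, step validation", {
  set.seed(1)
  f <- generate_wlc_fibril(1e9, 500, 5)
  t_mat <- diff(f$points)
  t_mat <- t_mat / sqrt(rowSums(t_mat^2))
  angles <- acos(pmin(1, rowSums(t_mat[-1, ] * t_mat[-nrow(t_mat), ])))
  expect_lt(max(angles), 1e-3)

  set.seed(9); a <- generate_wlc_fibril(500, 300, 5)
  set.seed(9); b <- generate_wlc_fibril(500, 300, 5)
  expect_identical(a$points, b$points)

  expect_error(generate_wlc_fibril(40, 300, 5), "too coarse")
  expect_error(generate_wlc_fibril(1000, 8, 5), ">= 2 \\* step")
})

test_that("WLC ensemble decay matches the closed form at l = L_p", {
  set.seed(14)
  fl <- lapply(1:400, function(i) generate_wlc_fibril(500, 1000, 5, id = i))
  cu <- tangent_correlation(fl, 5, 500)
  i <- which.min(abs(cu$l - 500))
  expect_equal(cu$mean_cos[i], exp(-1), tolerance = 0.05)
})

test_that("generate_scene: empty scene, determinism, planted clustering", {
  sp0 <- scene_spec(extent_nm = c(250, 250, 100), organelles = list(),
                    n_fibrils = 10, rng_seed = 3)
  g0 <- generate_scene(sp0)
  expect_length(g0$fibrils, 10)
  expect_equal(cytosolic_fibril_density(g0$scene, list())$cytosolic_volume_nm3,
               250 * 250 * 100)
  g0b <- generate_scene(sp0)
  expect_equal(g0$fibrils[[5]]$points, g0b$fibrils[[5]]$points)

  sp2 <- scene_spec(extent_nm = c(300, 300, 150), voxel_size = 2,
                    organelles = replicate(2, list(shape = "sphere",
                                                   radius = 30),
                                           simplify = FALSE),
                    placement = "clustered", cluster_spacing_nm = 10,
                    n_fibrils = 0, rng_seed = 11)
  g2 <- generate_scene(sp2)
  im <- inter_membrane_distances(g2$scene)
  # planted surface gap below 10 nm; voxel-center discretization adds <= 2 voxels
  expect_lte(min(im$distance_nm), 10 + 2 * g2$scene$voxel_size)
})

test_that("organelle shapes voxelize and fibrils avoid lumina", {
  sp <- scene_spec(extent_nm = c(300, 300, 140), voxel_size = 5,
                   organelles = list(list(shape = "sphere", radius = 25),
                                     list(shape = "ellipsoid",
                                          semi_axes = c(40, 25, 20)),
                                     list(shape = "tube", radius = 12,
                                          half_length = 40)),
                   n_fibrils = 12, rng_seed = 21)
  g <- generate_scene(sp)
  expect_setequal(organelle_ids(g$scene), 1:3)
  lab <- g$scene$label_volume
  vs <- g$scene$voxel_size
  for (f in g$fibrils) {
    ijk <- round(f$points / vs) + 1
    expect_true(all(lab[ijk] == 0L))
  }
})

test_that("membrane attraction plants a close-contact excess (paired seeds)", {
  mass_at <- function(strength, seed) {
    sp <- scene_spec(extent_nm = c(200, 200, 100), voxel_size = 5,
                     organelles = replicate(2, list(shape = "sphere",
                                                    radius = 20),
                                            simplify = FALSE),
                     n_fibrils = 25, mean_length_nm = 160,
                     attraction_strength = strength,
                     attraction_range_nm = 20, rng_seed = seed)
    g <- generate_scene(sp)
    fld <- membrane_distance_field(g$scene)
    contact_mass(fibril_membrane_distances(g$fibrils, fld)$distance_nm)
  }
  wins <- vapply(1:8, function(s) mass_at(0.9, s) > mass_at(0, s), logical(1))
  expect_gte(sum(wins), 7)
})

test_that("gold fixture arithmetic and ordering guard", {
  x <- generate_gold_fixture(7, 4.8, jitter = 0, n_labels = 10)
  expect_equal(diff(x), rep(33.6, 9))
  x1 <- generate_gold_fixture(1, 4.8, jitter = 0, n_labels = 5)
  expect_equal(mean(diff(x1)), 4.8)
  expect_error(generate_gold_fixture(7, 4.8, jitter = 20), "ordering")

  # equal-weight mixture of k = 7 and k = 8 labelling, jittered
  set.seed(33)
  d7 <- diff(generate_gold_fixture(7, 4.8, jitter = 2, n_labels = 200))
  d8 <- diff(generate_gold_fixture(8, 4.8, jitter = 2, n_labels = 200))
  m <- mean(c(d7, d8))
  expect_equal(m, 36.0, tolerance = 0.02)
  expect_gt(gold_label_periodicity(m, 4.8), 7)
  expect_lt(gold_label_periodicity(m, 4.8), 8)
})

test_that("scene exchange formats round-trip", {
  sp <- scene_spec(extent_nm = c(200, 200, 100), voxel_size = 5,
                   organelles = list(list(shape = "sphere", radius = 20)),
                   n_fibrils = 5, rng_seed = 8)
  g <- generate_scene(sp)
  dir <- file.path(tempdir(), "scene_rt")
  paths <- write_scene(g, dir)
  sc <- read_label_volume(paths["mrc"])
  expect_identical(sc$label_volume, g$scene$label_volume)
  expect_equal(sc$voxel_size, g$scene$voxel_size)
  fl <- read_fibrils(paths["csv"])
  expect_length(fl, 5)
  expect_equal(fl[[2]]$points, g$fibrils[[2]]$points, tolerance = 1e-6,
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$spec$L_p, 1000)
})
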