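test_that("distance field: single voxel, parallel planes, field properties", {
  lab <- array(0L, c(21, 21, 21)); lab[11, 11, 11] <- 1L
  sc <- tomogram_scene(lab, voxel_size = 1)
  fld <- membrane_distance_field(sc)
  expect_equal(fld$field[1, 1, 1], sqrt(300), tolerance = 1e-9)
  expect_equal(fld$field[11, 11, 11], 0)

  # two parallel membrane planes 20 voxels apart -> 10 nm at the midplane
  lab2 <- array(0L, c(9, 9, 25)); lab2[, , 2] <- 1L; lab2[, , 22] <- 2L
  sc2 <- tomogram_scene(lab2, voxel_size = 1)
  fld2 <- membrane_distance_field(sc2)
  expect_equal(fld2$field[5, 5, 12], 10)

  # non-negative, zero exactly on membrane voxels, 1-Lipschitz along x
  mask <- .membrane_mask_for_test(sc2)
  expect_true(all(fld2$field >= 0))
  expect_true(all(fld2$field[mask] == 0))
  dx <- abs(apply(fld2$field, c(2, 3), diff))
  expect_true(all(dx <= 1 + 1e-9))
})

test_that("EDT equals the brute-force oracle on random small scenes", {
  set.seed(61)
  for (rep in 1:5) {
    d <- sample(10:24, 3, replace = TRUE)
    lab <- array(0L, d)
    lab[sample(prod(d), 40)] <- 1L
    vs <- runif(1, 0.5, 3)
    sc <- tomogram_scene(lab, voxel_size = vs)
    fld <- membrane_distance_field(sc)
    # oracle: distance to the boundary voxels (all labelled voxels here are
    # boundary because isolated)
    mask <- array(FALSE, d)
    for (id in names(sc$membrane_points)) {
      ijk <- round(sc$membrane_points[[id]] / vs) + 1
      mask[ijk] <- TRUE
    }
    expect_equal(fld$field, bf_distance_field(mask, vs), tolerance = 1e-9)
  }
})

test_that("fibril-membrane distances: point lookups and sphere chord geometry", {
  lab <- array(0L, c(21, 21, 21)); lab[11, 15, 11] <- 1L
  sc <- tomogram_scene(lab, voxel_size = 1)
  fld <- membrane_distance_field(sc)
  f <- fibril(rbind(c(10, 10, 10), c(10, 10, 12)), id = "q")
  dd <- fibril_membrane_distances(list(f), fld, resample = FALSE)
  expect_equal(dd$distance_nm[1], 4, tolerance = 1e-9)

  # diameter chord of a spherical shell, radius 50 nm
  dims <- c(61, 61, 61)
  lab2 <- make_sphere_label(dims, c(31, 31, 31), 25, 1L)
  sc2 <- tomogram_scene(lab2, voxel_size = 2)
  fld2 <- membrane_distance_field(sc2)
  chord <- fibril(rbind(c(10, 60, 60), c(110, 60, 60)), id = "chord")
  dd2 <- fibril_membrane_distances(list(chord), fld2, step = 1)
  expect_lt(min(dd2$distance_nm), 3)            # crosses the shell
  expect_equal(max(dd2$distance_nm), 50, tolerance = 0.1)  # centre

  # empty input, and out-of-grid points are named
  expect_equal(nrow(fibril_membrane_distances(list(), fld)), 0)
  bad <- fibril(rbind(c(-50, 0, 0), c(500, 0, 0)), id = "bad")
  expect_error(fibril_membrane_distances(list(bad), fld, resample = FALSE),
               "bad")
})

test_that("inter-membrane distances: two spheres, three organelles, contact", {
  sc <- two_sphere_scene(voxel_size = 2, r1 = 15, r2 = 20, gap_vox = 10)
  im <- inter_membrane_distances(sc)
  # surface gap 10 voxels = 20 nm, voxel discretization within ~2 voxels
  expect_equal(min(im$distance_nm), 20, tolerance = 0.2)
  # oracle equivalence: exact match with brute force over membrane points
  for (id in names(sc$membrane_points)) {
    other <- do.call(rbind,
                     sc$membrane_points[setdiff(names(sc$membrane_points), id)])
    want <- bf_nearest(sc$membrane_points[[id]], other)
    got <- im$distance_nm[im$organelle == id]
    expect_equal(got, want, tolerance = 1e-9)
  }

  # A-B close, C far away
  lab <- array(0L, c(40, 12, 12))
  lab[2:4, 5:7, 5:7] <- 1L; lab[7:9, 5:7, 5:7] <- 2L; lab[36:38, 5:7, 5:7] <- 3L
  sc3 <- tomogram_scene(lab, voxel_size = 10)
  im3 <- inter_membrane_distances(sc3)
  expect_lt(min(im3$distance_nm[im3$organelle %in% c("1", "2")]), 35)
  expect_gt(min(im3$distance_nm[im3$organelle == "3"]), 250)

  # touching cubes: distinct label boundaries one voxel apart
  lab4 <- array(0L, c(12, 8, 8))
  lab4[2:5, 2:5, 2:5] <- 1L; lab4[6:9, 2:5, 2:5] <- 2L
  sc4 <- tomogram_scene(lab4, voxel_size = 3)
  expect_equal(min(inter_membrane_distances(sc4)$distance_nm), 3)

  # fewer than two organelles is undefined
  lab5 <- array(0L, c(8, 8, 8)); lab5[3:5, 3:5, 3:5] <- 1L
  expect_error(inter_membrane_distances(tomogram_scene(lab5, 1)), "undefined")
})

test_that("randomize_fibrils: uniformity, determinism, shape preservation", {
  sc <- tomogram_scene(array(0L, c(30, 30, 30)), voxel_size = 10)
  f <- straight_fibril(c(0, 0, 0), 40, n = 5)
  set.seed(8)
  draws <- randomize_fibrils(sc, rep(list(f), 2000))
  expect_true(all(attr(draws, "retries") == 0))   # no organelles: first draw
  cents <- t(vapply(draws, function(g) colMeans(g$points), numeric(3)))
  # the admissible centroid box depends on the drawn rotation, so marginal
  # uniformity only holds on the core box every rotation admits: bounds
  # shrunk by the fibril half-extent (20 nm)
  core_lo <- 0 + 20; core_hi <- 290 - 20
  core <- cents[apply(cents > core_lo & cents < core_hi, 1, all), ]
  for (j in 1:3) {
    cnt <- table(cut(core[, j], breaks = seq(core_lo, core_hi,
                                             length.out = 11)))
    expect_gt(suppressWarnings(chisq.test(cnt)$p.value), 1e-4)
  }
  # rigid motion: lengths and tangent statistics unchanged
  lens <- vapply(draws[1:50], fibril_length, numeric(1))
  expect_true(all(abs(lens - fibril_length(f)) < 1e-9))

  set.seed(77); a <- randomize_fibrils(sc, list(f))
  set.seed(77); b <- randomize_fibrils(sc, list(f))
  expect_equal(a[[1]]$points, b[[1]]$points)

  too_long <- straight_fibril(c(0, 0, 0), 5000)
  expect_error(randomize_fibrils(sc, list(too_long), max_retries = 50),
               "could not place")
})

test_that("persistence statistics are invariant under the null's rigid motions", {
  set.seed(12)
  sc <- tomogram_scene(array(0L, c(40, 40, 40)), voxel_size = 10)
  fl <- lapply(1:20, function(i) generate_wlc_fibril(1000, 200, 5, id = i))
  cu0 <- tangent_correlation(fl, 5, 150)
  moved <- randomize_fibrils(sc, fl)
  cu1 <- tangent_correlation(moved, 5, 150)
  expect_equal(cu1$mean_cos, cu0$mean_cos, tolerance = 1e-9)
})

test_that("null ensemble is reproducible and seed-sensitive", {
  sc <- two_sphere_scene()
  set.seed(101)
  fl <- lapply(1:5, function(i) generate_wlc_fibril(1000, 110, 5, id = i))
  fl <- randomize_fibrils(sc, fl)
  ne1 <- null_ensemble(sc, fl, n_simulations = 3, seed = 42)
  ne2 <- null_ensemble(sc, fl, n_simulations = 3, seed = 42)
  ne3 <- null_ensemble(sc, fl, n_simulations = 3, seed = 43)
  expect_equal(ne1$samples, ne2$samples)
  expect_false(isTRUE(all.equal(ne1$samples, ne3$samples)))
  expect_equal(ne1$n_simulations, 3L)
})

test_that("distance profiles and bands follow order statistics", {
  p <- distance_profile(c(1, 3, 250), bin_width = 2, max_nm = 200)
  expect_equal(sum(p$freq), 1)
  expect_equal(p$n_overflow, 1)        # 250 clamps into the last bin
  expect_equal(p$sample_count, 3)

  mk <- function(v) structure(list(bin_edges = 0:4, freq = rep(v, 4),
                                   sample_count = 10, n_overflow = 0,
                                   source = "simulated", tomogram = NA),
                              class = "distance_profile")
  # identical curves -> degenerate band
  b0 <- band(rep(list(mk(0.25)), 10))
  expect_true(all(b0$p05 == b0$p95))
  # 100 curves valued i/100 per bin
  b <- band(lapply(1:100, function(i) mk(i / 100)))
  expect_equal(b$median[1], 0.505)
  expect_true(b$p05[1] >= 0.05 && b$p05[1] <= 0.06)
  expect_true(b$p95[1] >= 0.95 && b$p95[1] <= 0.96)
  # single curve: band equals the curve
  b1 <- band(list(mk(0.1)))
  expect_equal(b1$median, b1$p05)
  expect_error(band(list(mk(0.1), structure(list(bin_edges = 0:5,
    freq = rep(0.2, 5), sample_count = 1, n_overflow = 0,
    source = "simulated", tomogram = NA), class = "distance_profile"))),
    "mismatched")
})

test_that("ks_compare: degenerate cases and truncation bookkeeping", {
  x <- runif(200, 0, 15)
  r <- ks_compare(x, x)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)

  r2 <- ks_compare(runif(100, 0, 5), runif(100, 10, 20))
  expect_equal(r2$D, 1)

  r3 <- ks_compare(c(5, 10, 30, 40), c(15, 25, 35))
  expect_equal(r3$n_a, 2)
  expect_equal(r3$n_dropped_a, 2)
  expect_equal(r3$n_b, 1)

  expect_error(ks_compare(c(30, 40), c(5, 10)), "no mass below")
})

test_that("ks type-I error is calibrated on iid samples", {
  set.seed(202)
  rej <- mean(replicate(600, {
    ks_compare(runif(500, 0, 20), runif(500, 0, 20))$p < 0.05
  }))
  # 99% binomial band around 0.05 with n = 600
  expect_gt(rej, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 600))
  expect_lt(rej, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 600))
})
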