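test_that("tangent correlation: straight fibril and circle closed forms", {
  f <- straight_fibril(c(0, 0, 0), 500, n = 101)
  cu <- tangent_correlation(list(f), step = 5, max_sep = 200)
  expect_true(all(abs(cu$mean_cos - 1) < 1e-12))

  # planar circle radius 100: mean cos at arc separation l is cos(l / R)
  th <- seq(0, 1.8 * pi, by = 0.002)
  circ <- fibril(cbind(100 * cos(th), 100 * sin(th), 0))
  cu2 <- tangent_correlation(list(circ), step = 1, max_sep = 200)
  i <- which.min(abs(cu2$l - pi * 50))   # l = 157.08 -> cos(pi/2) = 0
  expect_lt(abs(cu2$mean_cos[i]), 0.02)
  j <- which.min(abs(cu2$l - 100))
  expect_equal(cu2$mean_cos[j], cos(1), tolerance = 0.01)
})

test_that("noiseless inversion recovers L_p exactly; rigid input errors", {
  l <- seq(10, 200, 10)
  cu <- structure(list(l = l, mean_cos = exp(-l / 500),
                       n_pairs = rep(100L, length(l)), step = 10),
                  class = "correlation_curve")
  ft <- fit_persistence_length(cu)
  expect_equal(ft$L_p_nm, 500, tolerance = 1e-9)
  expect_equal(ft$fit_intercept, 0, tolerance = 1e-12)

  cu_flat <- structure(list(l = l, mean_cos = rep(1, length(l)),
                            n_pairs = rep(100L, length(l)), step = 10),
                       class = "correlation_curve")
  expect_error(fit_persistence_length(cu_flat), "no measurable decay")

  cu_neg <- structure(list(l = l[1:3], mean_cos = c(0.5, -0.1, -0.2),
                           n_pairs = rep(10L, 3), step = 10),
                      class = "correlation_curve")
  expect_error(fit_persistence_length(cu_neg), "at least 3 bins")
})

test_that("Young's modulus closed form", {
  kB <- 1.380649e-23
  E_ref <- (1e-6 * kB * 295) / (pi * (5e-9)^4 / 4)   # L_p = 1 um, r = 5 nm
  expect_equal(young_modulus(1000), E_ref, tolerance = 1e-12)
  expect_equal(signif(young_modulus(1000), 3), 8.30e6)
  # fit carries E consistent with its L_p
  l <- seq(10, 200, 10)
  cu <- structure(list(l = l, mean_cos = exp(-l / 1000),
                       n_pairs = rep(100L, length(l)), step = 10),
                  class = "correlation_curve")
  ft <- fit_persistence_length(cu)
  expect_equal(ft$E_Pa, young_modulus(ft$L_p_nm), tolerance = 1e-12)
  expect_equal(ft$constants$I_m4, pi * (5e-9)^4 / 4)
})

test_that("scale equivariance: scaling coordinates scales L_p and E", {
  set.seed(21)
  fl <- lapply(1:60, function(i) generate_wlc_fibril(800, 800, 5, id = i))
  fl3 <- lapply(fl, function(f) fibril(f$points * 3, id = f$id,
                                       radius = f$radius))
  ft1 <- fit_persistence_length(tangent_correlation(fl, 5, 400))
  ft3 <- fit_persistence_length(tangent_correlation(fl3, 15, 1200))
  expect_equal(ft3$L_p_nm / ft1$L_p_nm, 3, tolerance = 1e-6)
  expect_equal(ft3$E_Pa / ft1$E_Pa, 3, tolerance = 1e-6)
})

test_that("WLC ensemble: decay matches target and curve is monotone in trend", {
  set.seed(31)
  fl <- lapply(1:200, function(i) generate_wlc_fibril(1000, 1000, 5, id = i))
  cu <- tangent_correlation(fl, 5, 500)
  expect_equal(cu$mean_cos, exp(-cu$l / 1000), tolerance = 0.03,
               ignore_attr = TRUE)
  # binned means non-increasing up to sampling noise
  expect_true(all(diff(cu$mean_cos) < 0.01))
  ft <- fit_persistence_length(cu)
  expect_equal(ft$L_p_nm, 1000, tolerance = 0.15)
  # pooling invariance: two half-ensembles give compatible fits
  ft_a <- fit_persistence_length(tangent_correlation(fl[1:100], 5, 500))
  ft_b <- fit_persistence_length(tangent_correlation(fl[101:200], 5, 500))
  expect_lt(abs(ft_a$L_p_nm - ft_b$L_p_nm) / ft$L_p_nm, 0.25)
})

test_that("bins with non-positive mean cosine are excluded and logged", {
  l <- seq(10, 100, 10)
  mc <- exp(-l / 30); mc[9:10] <- c(-0.01, -0.02)
  cu <- structure(list(l = l, mean_cos = mc, n_pairs = rep(50L, 10), step = 10),
                  class = "correlation_curve")
  ft <- fit_persistence_length(cu)
  expect_equal(ft$excluded_bins, c(90, 100))
  expect_equal(ft$L_p_nm, 30, tolerance = 1e-9)
})
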