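# PDD/profile analysis and comparison statistics

test_that("PDD extraction normalizes and handles closed forms", {
  # flat dose: flat curve at 100 whichever normalization
  flat <- structure(data.frame(x = 0, y = 0, z = 16:25, dose = 1,
                               stderr = 0),
                    class = c("dose_result", "data.frame"))
  pdd <- extract_pdd(flat, 15)
  expect_equal(pdd$pdd, rep(100, 10), tolerance = 1e-9)
  # exponential exp(-0.2 d): surface-normalized value at d = 5 is 100/e
  expo <- structure(data.frame(x = 0, y = 0, z = 15 + 1:10,
                               dose = exp(-0.2 * (1:10)), stderr = 0),
                    class = c("dose_result", "data.frame"))
  pdd2 <- extract_pdd(expo, 15)
  expect_equal(pdd2$pdd[pdd2$depth_cm == 5], 100 * exp(-1), tolerance = 0.1)
  off <- structure(data.frame(x = 1, y = 0, z = 16:18, dose = 1, stderr = 0),
                   class = c("dose_result", "data.frame"))
  expect_error(extract_pdd(off, 15), "central axis")
})

test_that("surface extrapolation is exact on polynomials and unbiased on noisy data", {
  d <- 1:6
  cubic <- 120 - 18 * d + 2.2 * d^2 - 0.11 * d^3
  expect_equal(surface_extrapolate(data.frame(depth_cm = d, pdd = cubic),
                                   order = 3, k = 6), 120, tolerance = 1e-9)
  lin <- data.frame(depth_cm = c(1, 2), pdd = c(90, 80))
  expect_equal(surface_extrapolate(lin, order = 1, k = 2), 100,
               tolerance = 1e-9)
  expect_error(surface_extrapolate(lin, order = 3, k = 2),
               "underdetermined")
  # 1% multiplicative noise on an exponential: mean over 20 repeats within
  # 2% of the closed-form surface value
  set.seed(8)
  truth <- exp(-0.2 * d)
  est <- replicate(20, {
    y <- truth * (1 + rnorm(6, 0, 0.01))
    surface_extrapolate(data.frame(depth_cm = d, pdd = y), order = 3, k = 5)
  })
  expect_lt(abs(mean(est) - 1), 0.02)
})

test_that("percent differences match hand arithmetic and obey invariances", {
  a <- data.frame(x = 1:3, y = c(100, 50, 25))
  b <- data.frame(x = 1:3, y = c(100, 48, 26))
  cs <- percent_difference_stats(a, b)
  expect_equal(cs$per_point$pd, c(0, 100 * 2 / 48, -100 * 1 / 26),
               tolerance = 1e-9)
  expect_equal(cs$mean_abs, mean(c(0, 4.1667, 3.8462)), tolerance = 1e-3)
  expect_equal(cs$min, -3.8462, tolerance = 1e-3)
  expect_equal(cs$max, 4.1667, tolerance = 1e-3)
  # identical curves: all zero
  z <- percent_difference_stats(a, a)
  expect_true(all(z$per_point$pd == 0))
  expect_equal(c(z$min, z$max, z$mean_abs, z$sd_abs), c(0, 0, 0, 0))
  # uniform offset: every PD = 2, sd 0
  a2 <- a; a2$y <- 1.02 * a$y
  u <- percent_difference_stats(a2, a)
  expect_equal(u$per_point$pd, rep(2, 3), tolerance = 1e-12)
  expect_equal(u$sd_abs, 0)
  # normalization invariance
  s1 <- percent_difference_stats(a, b)
  a3 <- a; a3$y <- a$y * 7.3; b3 <- b; b3$y <- b$y * 7.3
  s2 <- percent_difference_stats(a3, b3)
  expect_equal(s1$per_point$pd, s2$per_point$pd, tolerance = 1e-12)
  expect_error(percent_difference_stats(a, data.frame(x = 9:10, y = 1:2)),
               "overlap")
})

test_that("quadrature combination reproduces the reported uncertainty arithmetic", {
  expect_equal(quadrature_uncertainty(c(2.1, 0.3)), 2.1)
  expect_equal(quadrature_uncertainty(c(3, 4)), 5)
  expect_equal(quadrature_uncertainty(1.7), 1.7)
  expect_error(quadrature_uncertainty(c(1, -2)), ">= 0")
})

test_that("reference comparison refuses mismatched techniques and handles shifts", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# kvp: 120", "# hvl_mm_al: 4.18", "# ssd_cm: 15",
               "# field: 5 cm circle", "depth_cm,pdd",
               paste(1:10, round(100 * exp(-0.25 * (1:10)), 4), sep = ",")),
             path)
  ref <- read_reference_pdd(path)
  expect_equal(attr(ref, "kvp"), 120)
  curve <- depth_dose_curve(1:10, 100 * exp(-0.25 * (1:10)))
  cs <- compare_to_reference(curve, ref, technique = list(kvp = 120,
                                                          ssd_cm = 15))
  expect_lt(cs$mean_abs, 1e-3)
  # +5% reference shift: every PD close to 100*(1/1.05 - 1)
  shifted <- curve; shifted$pdd <- curve$pdd * 1.05
  cs2 <- compare_to_reference(ref, shifted,
                              technique = list())
  expect_equal(unique(round(cs2$per_point$pd, 2)), -4.76)
  expect_error(compare_to_reference(curve, ref,
                                    technique = list(kvp = 140,
                                                     ssd_cm = 15)),
               "technique mismatch.*kvp")
})

test_that("profile curves normalize to the central axis", {
  p <- profile_curve(c(-2, -1, 0, 1, 2), c(0.4, 0.9, 1.0, 0.88, 0.41), 1)
  expect_equal(p$value[p$position_cm == 0], 100)
  expect_error(profile_curve(c(-1, 1), c(1, 1), 1), "position 0")
})

test_that("profile comparison can exclude the region beyond the aperture edge", {
  x <- seq(-4, 4, by = 1)
  a <- data.frame(x = x, y = c(5, 60, 98, 100, 100, 100, 97, 58, 6))
  b <- data.frame(x = x, y = c(9, 55, 97, 100, 100, 100, 98, 63, 3))
  full <- percent_difference_stats(a, b)
  inner <- percent_difference_stats(a, b, x_window = 2.5)
  expect_lt(inner$mean_abs, full$mean_abs)
  expect_true(all(abs(inner$per_point$x) <= 2.5))
})
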