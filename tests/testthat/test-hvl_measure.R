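# Three-point semilogarithmic HVL determination

test_that("exact exponential data reproduce the closed-form HVL", {
  mu <- 0.3  # per mm
  t <- c(0, 1, 2, 3)
  s <- transmission_series(t, exp(-mu * t))
  expect_equal(hvl_three_point(s), log(2) / mu, tolerance = 1e-6)
})

test_that("an exact 50% reading is returned verbatim", {
  s <- transmission_series(c(0, 1.0, 2.2, 3.1), c(1, 0.6, 0.5, 0.4))
  expect_equal(hvl_three_point(s), 2.2, tolerance = 1e-9)
})

test_that("result is invariant to rescaling all readings", {
  t <- c(0, 1.5, 2.5, 3.5, 4.5)
  r <- exp(-0.28 * t) * (1 + 0.01 * t)  # mildly hardened shape
  s1 <- transmission_series(t, r)
  s2 <- transmission_series(t, 137.4 * r)
  expect_equal(hvl_three_point(s1), hvl_three_point(s2), tolerance = 1e-12)
})

test_that("polyenergetic forward model agrees with the spectral HVL", {
  sp <- tuned_120()$spectrum
  h_true <- air_kerma_hvl(sp)
  s <- transmission_series(c(0, 3, 4, 5), kerma_transmission(sp, c(0, 3, 4, 5)))
  expect_lt(abs(hvl_three_point(s) - h_true), 0.05)
  # property: brackets offset up to +/-30% of the true HVL stay within 0.05 mm
  for (kvp in c(80, 120, 150)) {
    spk <- nominal_spectrum(kvp)
    hk <- air_kerma_hvl(spk)
    for (off in list(c(-0.3, -0.1, 0.15), c(-0.25, 0.05, 0.3),
                     c(-0.15, 0.1, 0.25))) {
      th <- c(0, hk * (1 + off))
      sk <- transmission_series(th, kerma_transmission(spk, th))
      expect_lt(abs(hvl_three_point(sk) - hk), 0.05)
    }
  }
})

test_that("error paths: missing bracket, non-monotone readings, too few points", {
  expect_error(hvl_three_point(
    transmission_series(c(0, 1, 2, 3), c(1, 0.9, 0.8, 0.7))), "bracket")
  expect_error(hvl_three_point(
    transmission_series(c(0, 1, 2, 3), c(1, 0.6, 0.65, 0.4))),
    "non-monotone")
  expect_error(hvl_three_point(
    transmission_series(c(0, 2, 3), c(1, 0.6, 0.4))), "three")
})

test_that("hvl_map sorts positions, propagates errors with position, and handles one series", {
  sp <- tuned_120()$spectrum
  th <- c(0, 3, 4, 5)
  mk <- function(x) transmission_series(th, kerma_transmission(sp, th),
                                        position = c(x, 0), axis = "inline")
  m <- hvl_map(list(mk(3), mk(-3), mk(0)))
  expect_equal(m$position_cm, c(-3, 0, 3))
  expect_equal(diff(m$hvl_mm), c(0, 0), tolerance = 1e-9)  # identical series
  one <- hvl_map(list(mk(0)))
  expect_equal(nrow(one), 1L)
  bad <- transmission_series(c(0, 1, 2, 3), c(1, 0.9, 0.8, 0.7),
                             position = c(6, 0), axis = "inline")
  expect_error(hvl_map(list(mk(0), bad)), "position 6")
})

test_that("heel-gradient spectra give a monotone inline HVL map", {
  th <- make_heel_source(hvl_gradient_per_cm = 0.05, seed = 11)
  series <- lapply(seq_along(th$spectra$positions_cm), function(i) {
    sp <- th$spectra$spectra[[i]]
    h <- air_kerma_hvl(sp)
    synthetic_transmission(sp, c(0, h - 1, h - 0.4, h + 0.4, h + 1),
                           noise_sd = 0, seed = 5,
                           position = c(th$spectra$positions_cm[i], 0),
                           axis = "inline")
  })
  m <- hvl_map(series)
  expect_true(all(diff(m$hvl_mm) > 0))
  # matches the generating truth's ordering and values
  expect_equal(m$hvl_mm, th$truth$station_hvl, tolerance = 0.02)
})

test_that("transmission CSV round trip preserves the series grouping", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("thickness_mm,reading,position_cm,axis",
               "0,1.0,0,inline", "3,0.62,0,inline", "4,0.52,0,inline",
               "5,0.43,0,inline",
               "0,1.0,3,inline", "3,0.64,3,inline", "4,0.54,3,inline",
               "5,0.45,3,inline"), path)
  lst <- read_transmission_csv(path)
  expect_length(lst, 2L)
  expect_true(all(vapply(lst, inherits, TRUE, "transmission_series")))
})
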