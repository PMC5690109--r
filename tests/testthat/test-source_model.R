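# Effective point source: fluence recovery, forward model, sampling

test_that("identical spectra at all stations make fluence equal the dose scan", {
  sp <- tuned_120()$spectrum
  stations <- spectrum_set(c(-2, 0, 2), list(sp, sp, sp))
  pos <- seq(-2.5, 2.5, by = 0.5)
  d <- 1 - 0.05 * abs(pos)
  scan <- inair_scan("inline", pos, d, 5, 15)
  f <- fluence_from_inair(scan, stations)
  expect_equal(f$fluence, scan$relative_dose)   # spectral ratio cancels
  expect_equal(f$fluence[f$position_cm == 0], 1)
})

test_that("two-position toy matches the hand-computed spectral correction", {
  u0 <- mono_spectrum(60)
  ux <- mono_spectrum(80)
  stations <- spectrum_set(c(0, 2), list(u0, ux))
  scan <- inair_scan("inline", c(0, 2), c(1, 0.9), 4, 15)
  f <- fluence_from_inair(scan, stations)
  hand <- 0.9 * (mass_energy_absorption("air", 60.25) * 60.25) /
    (mass_energy_absorption("air", 80.25) * 80.25)
  expect_equal(f$fluence[f$position_cm == 2], hand, tolerance = 1e-12)
})

test_that("characterization inverts the forward model (round trip identity)", {
  th <- make_heel_source(hvl_gradient_per_cm = 0.04, seed = 3)
  for (ax in c("inline", "crossline")) {
    scan <- synthetic_inair_scan(th, ax, noise_sd = 0, seed = 1)
    f <- fluence_from_inair(scan, th$spectra)
    truth <- if (ax == "inline") {
      approx(th$truth$x_pos, th$truth$x_val, f$position_cm)$y
    } else {
      approx(th$truth$y_pos, th$truth$y_val, f$position_cm)$y
    }
    expect_lt(max(abs(f$fluence - truth)), 1e-6)
  }
})

test_that("in-air dose is separable when the spectrum varies only with x", {
  th <- make_heel_source(hvl_gradient_per_cm = 0.05, seed = 4)
  for (p in list(c(1.2, -2.3), c(-3.7, 0.4), c(5, 5))) {
    lhs <- inair_dose_at(th, p[1], p[2]) * inair_dose_at(th, 0, 0)
    rhs <- inair_dose_at(th, p[1], 0) * inair_dose_at(th, 0, p[2])
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(inair_dose_at(th, 30, 0), "outside")
})

test_that("build_source rejects scans narrower than the aperture", {
  sp <- tuned_120()$spectrum
  pos <- seq(-1.5, 1.5, by = 0.5)
  scan <- inair_scan("inline", pos, rep(1, 7), 5, 15)
  expect_error(build_source(120, 15, 5, scan, scan,
                            spectrum_set(0, list(sp))),
               "narrower than the aperture")
})

test_that("emissions follow the fluence density over the aperture disk", {
  th <- make_heel_source(hvl_gradient_per_cm = 0, seed = 5,
                         applicator_diameter_cm = 15)
  set.seed(42)
  em <- sample_emission(th, 100000)
  # all plane positions inside the aperture and all rays hit it at the SSD
  a <- th$applicator_diameter_cm / 2
  r2 <- rowSums(em$plane_xy^2)
  expect_true(all(r2 <= a^2 + 1e-9))
  plane <- em$direction * (th$ssd_cm / em$direction[, 3])
  expect_equal(plane[, 1], em$plane_xy[, "x"], tolerance = 1e-9)
  expect_true(all(em$energy_keV <= th$kvp))
  expect_true(all(em$weight == 1))
  # chi^2 of the x-marginal against X(x) * integral of Y over the disk chord
  br <- seq(-a, a, length.out = 21)
  counts <- table(cut(em$plane_xy[, "x"], br))
  dens <- vapply(seq_len(20), function(i) {
    xs <- seq(br[i], br[i + 1], length.out = 25)
    ch <- sqrt(pmax(0, a^2 - xs^2))
    f <- vapply(seq_along(xs), function(j) {
      ys <- seq(-ch[j], ch[j], length.out = 51)
      if (ch[j] <= 0) return(0)
      sum(fluence_at(th$fluence, rep(xs[j], 51), ys)) * (2 * ch[j] / 50)
    }, numeric(1))
    mean(f) * (br[i + 1] - br[i])
  }, numeric(1))
  p <- suppressWarnings(chisq.test(as.numeric(counts),
                                   p = dens / sum(dens))$p.value)
  expect_gt(p, 0.01)
})

test_that("a concentrated fluence map sends every ray through its support", {
  sp <- tuned_120()$spectrum
  pos <- c(-0.02, 0, 0.02)
  scan_x <- inair_scan("inline", pos, c(0, 1, 0), 0.04, 15)
  scan_y <- inair_scan("crossline", pos, c(0, 1, 0), 0.04, 15)
  src <- build_source(120, 15, 0.04, scan_x, scan_y,
                      spectrum_set(0, list(sp)))
  set.seed(7)
  em <- sample_emission(src, 500)
  expect_true(all(abs(em$plane_xy) <= 0.02 + 1e-9))
})

test_that("source JSON serialization round-trips", {
  th <- make_heel_source(hvl_gradient_per_cm = 0.05, seed = 6,
                         applicator_diameter_cm = 5, ssd_cm = 15)
  path <- tempfile(fileext = ".json")
  write_source_json(th, path)
  back <- read_source_json(path)
  expect_equal(back$fluence$x_val, th$fluence$x_val)
  expect_equal(back$spectra$positions_cm, th$spectra$positions_cm)
  expect_equal(back$spectra$spectra[[1]]$fluence,
               th$spectra$spectra[[1]]$fluence)
  xs <- seq(-2, 2, by = 0.5)
  expect_equal(inair_dose_at(back, xs), inair_dose_at(th, xs),
               tolerance = 1e-12)
})
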