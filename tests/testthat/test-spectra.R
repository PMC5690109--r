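# Spectrum generation, HVL computation, tuning, import

test_that("generated spectra respect the peak potential and K-line threshold", {
  sp80 <- generate_spectrum(80)
  expect_true(all(sp80$fluence[sp80$bin_centers >= 80] == 0))
  # no K lines below the tungsten K edge: fluence is smooth there
  near <- abs(sp80$bin_centers - 59.32) < 0.3
  base <- abs(sp80$bin_centers - 60.8) < 0.3
  expect_lt(sp80$fluence[near][1], 2 * sp80$fluence[base][1])
  sp120 <- generate_spectrum(120)
  spike <- sp120$fluence[which.min(abs(sp120$bin_centers - 59.32))]
  shoulder <- sp120$fluence[which.min(abs(sp120$bin_centers - 61.3))]
  expect_gt(spike, 3 * shoulder)
  expect_true(all(sp120$bin_centers <= 120))
  expect_error(generate_spectrum(200), "kvp")
  expect_error(generate_spectrum(100, anode_angle_deg = 0), "anode angle")
})

test_that("beam hardening: added Al reduces fluence and raises mean energy", {
  sp <- generate_spectrum(100, added = filter_stack(Al = 1.0))
  sp2 <- attenuate_spectrum(sp, filter_stack(Al = 1.0))
  expect_lt(sum(sp2$fluence), sum(sp$fluence))
  expect_gt(mean_energy(sp2), mean_energy(sp))
})

test_that("filtration composes: attenuating after generation equals one combined stack", {
  a <- filter_stack(Cu = 0.05, Al = 0.9)
  b <- filter_stack(Al = 1.5)
  sp_then <- attenuate_spectrum(generate_spectrum(120, added = a), b)
  sp_once <- generate_spectrum(120, added = c(a, b))
  expect_equal(sp_then$fluence, sp_once$fluence, tolerance = 1e-12)
})

test_that("monoenergetic HVL matches the closed form ln2/mu", {
  sp <- mono_spectrum(60)
  mu <- mass_attenuation("Al", 60.25) * 2.699 / 10  # per mm at the bin center
  expect_equal(air_kerma_hvl(sp), log(2) / mu, tolerance = 1e-3)
})

test_that("transmission at the returned HVL is one half; second HVL >= first", {
  for (kvp in c(80, 120, 150)) {
    sp <- nominal_spectrum(kvp)
    h1 <- air_kerma_hvl(sp)
    expect_equal(kerma_transmission(sp, h1), 0.5, tolerance = 1e-6)
    h2 <- air_kerma_hvl(sp, order = 2)
    expect_gte(h2, h1)
  }
})

test_that("HVL grows strictly with added Al and the semilog transmission curve is convex", {
  sp0 <- generate_spectrum(120, added = filter_stack(Al = 1))
  hv <- vapply(c(0, 1, 2, 4), function(t) {
    air_kerma_hvl(attenuate_spectrum(sp0, filter_stack(Al = t)))
  }, numeric(1))
  expect_true(all(diff(hv) > 0))
  lt <- log(kerma_transmission(sp0, seq(0, 12, by = 1)))
  expect_true(all(diff(lt) < 0))           # strictly decreasing
  expect_true(all(diff(diff(lt)) > 0))     # convex in semilog (hardening)
})

test_that("tuning recovers a synthetic truth and is a fixed point", {
  added <- filter_stack(Al = 1.0)
  truth <- generate_spectrum(120, inherent = filter_stack(Al = 2.0),
                             added = added)
  target <- air_kerma_hvl(truth)
  fit <- tune_inherent_filtration(120, added = added,
                                  target_hvl_mm_al = target)
  expect_lt(abs(fit$hvl - target), 0.01)
  expect_lt(abs(fit$thickness_mm_al - 2.0), 0.05)
  # re-tuning to the tuned spectrum's own HVL returns the same thickness
  fit2 <- tune_inherent_filtration(120, added = added,
                                   target_hvl_mm_al = fit$hvl)
  expect_lt(abs(fit2$thickness_mm_al - fit$thickness_mm_al), 0.05)
})

test_that("unreachable tuning targets are reported with the bracket", {
  expect_error(
    tune_inherent_filtration(120, added = filter_stack(Al = 1.0),
                             target_hvl_mm_al = 0.5),
    "unreachable.*bracket", ignore.case = TRUE)
})

test_that("import resamples conservatively and round-trips through CSV", {
  sp <- nominal_spectrum(120)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  sp2 <- read_spectrum_csv(path, kvp = 120)
  expect_lt(abs(air_kerma_hvl(sp2) - air_kerma_hvl(sp)), 0.01)
  expect_equal(sum(sp2$fluence), sum(sp$fluence), tolerance = 1e-3)
  # single-row table gives a monoenergetic spectrum
  sp1 <- import_spectrum(59.9, 3.2)
  expect_equal(sum(sp1$fluence > 0), 1L)
  expect_equal(sum(sp1$fluence), 3.2)
  expect_error(import_spectrum(c(10, 9), c(1, 1)), "ascending")
})

test_that("imported fine-grid spectrum conserves kerma against fine quadrature", {
  sp_fine <- generate_spectrum(80, added = filter_stack(Al = 1.7),
                               bin_width = 0.05)
  k_fine <- kerma_integral(sp_fine) # 10x finer than default binning
  sp_re <- import_spectrum(sp_fine$bin_centers, sp_fine$fluence / 0.05,
                           bin_width = 0.5, kvp = 80)
  expect_equal(kerma_integral(sp_re) / sum(sp_re$fluence),
               k_fine / sum(sp_fine$fluence), tolerance = 1e-3)
})

test_that("kerma integral is linear and reduces to a single term for a line", {
  sp <- nominal_spectrum(120)
  sp2 <- energy_spectrum(sp$bin_centers, 2 * sp$fluence, sp$kvp)
  expect_equal(kerma_integral(sp2), 2 * kerma_integral(sp))
  m <- mono_spectrum(60)
  expect_equal(kerma_integral(m),
               mass_energy_absorption("air", 60.25) * 60.25)
  # default binning agrees with 10x finer quadrature (per unit fluence)
  spf <- generate_spectrum(120, added = filter_stack(Cu = 0.05, Al = 0.9),
                           bin_width = 0.05)
  expect_equal(kerma_integral(sp) / sum(sp$fluence),
               kerma_integral(spf) / sum(spf$fluence), tolerance = 2e-3)
})

test_that("spectrum invariants are enforced", {
  expect_error(energy_spectrum(c(1, 2, 3), c(0, 0, 0), 5), "positive bin")
  expect_error(energy_spectrum(c(1, 2, 3), c(1, 1, -1), 5), "nonnegative")
  expect_error(energy_spectrum(c(10, 20, 25), c(1, 1, 1), 30),
               "uniformly spaced")
  expect_error(energy_spectrum(c(10, 20, 30), c(1, 1, 1), 25),
               "above the peak")
  expect_error(filter_stack(Al = -1), ">= 0")
})
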