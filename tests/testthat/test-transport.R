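# Monte Carlo engine: free paths, interactions, scoring, conservation

test_that("free paths in homogeneous water are exponential (KS test)", {
  ph <- small_water_phantom(surface_z = 0, depth_cm = 60, half_width_cm = 6)
  e <- 60
  mu <- mass_attenuation("water", e)  # density 1
  fp <- sample_free_path(ph, c(0, 0, 1), c(0, 0, 1), e, 20000, seed = 1)
  expect_lt(mean(!is.finite(fp)), 1e-3)
  ks <- suppressWarnings(stats::ks.test(fp[is.finite(fp)], "pexp", rate = mu))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(fp[is.finite(fp)]), 1 / mu, tolerance = 0.03)
})

test_that("two-slab crossing probability matches the analytic attenuation", {
  ph <- build_water_phantom(c(10, 10, 20), c(1, 1, 0.3), surface_z = 0)
  ph$density[] <- rep(rep(c(1.0, 0.4), each = 10), each = 100)  # 3 cm + 3 cm
  e <- 50
  mu <- mass_attenuation("water", e)
  p_true <- exp(-mu * (3 * 1.0 + 3 * 0.4))
  n <- 40000
  fp <- sample_free_path(ph, c(0.05, 0.05, 0.01), c(0, 0, 1), e, n, seed = 2)
  p_hat <- mean(!is.finite(fp))
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("voxel chord lengths along any ray sum to the geometric chord", {
  ph <- build_water_phantom(c(7, 9, 11), c(0.31, 0.27, 0.19), surface_z = 2)
  set.seed(3)
  for (i in 1:25) {
    from <- c(runif(2, -0.8, 0.8), runif(1, 2.05, 2.6))
    to <- c(runif(2, -0.8, 0.8), runif(1, 3.0, 3.9))
    ch <- ray_chords(ph, from, to)
    expect_equal(sum(ch$length_cm), sqrt(sum((to - from)^2)),
                 tolerance = 1e-9)
  }
})

test_that("incoherent kinematics respect the Compton limits; coherent conserves energy", {
  for (e in c(20, 60, 100, 150)) {
    draws <- sample_interaction(e, "water", 4000, seed = e)
    inc <- draws[draws$kind == "incoherent", ]
    emin <- e / (1 + 2 * e / 510.99895)
    expect_true(all(inc$energy_out >= emin - 1e-9))
    expect_true(all(inc$energy_out <= e + 1e-9))
    coh <- draws[draws$kind == "coherent", ]
    if (nrow(coh)) expect_true(all(coh$energy_out == e))
  }
})

test_that("interaction kinds follow the bundled partial fractions", {
  e <- 30
  pp <- attenuation_partials("water")
  fr <- vapply(c("photo", "coherent", "incoherent"), function(k) {
    approx(log(pp$energies), pp[[k]], log(e))$y
  }, numeric(1))
  fr <- fr / sum(fr)
  n <- 50000
  draws <- sample_interaction(e, "water", n, seed = 9)
  obs <- table(factor(draws$kind, c("photoelectric", "coherent",
                                    "incoherent"))) / n
  for (i in 1:3) {
    expect_lt(abs(obs[[i]] - fr[[i]]), 4 * sqrt(fr[[i]] * (1 - fr[[i]]) / n))
  }
})

test_that("sampled Compton angles match the numeric Klein-Nishina pdf (chi^2)", {
  e <- 100
  draws <- sample_interaction(e, "water", 200000, seed = 4)
  ct <- draws$cos_theta[draws$kind == "incoherent"]
  br <- seq(-1, 1, length.out = 26)
  kn_pdf <- function(c0) {
    k <- e / 510.99895
    r <- 1 / (1 + k * (1 - c0))
    0.5 * r^2 * (1 / r + r - (1 - c0^2))
  }
  probs <- vapply(seq_len(25), function(i) {
    x <- seq(br[i], br[i + 1], length.out = 101)
    sum(kn_pdf(x)) * diff(br)[1] / 101
  }, numeric(1))
  counts <- table(cut(ct, br))
  p <- suppressWarnings(chisq.test(as.numeric(counts),
                                   p = probs / sum(probs))$p.value)
  expect_gt(p, 0.01)
})

test_that("primary-only slab transmission matches Beer-Lambert within 3 SE", {
  e <- 60
  tck <- 3.0  # cm of water
  src <- pencil_source(e)
  ph <- build_water_phantom(c(20, 20, 10), c(0.4, 0.4, tck / 10),
                            surface_z = 5)
  n <- 100000
  d <- compute_dose(src, ph, data.frame(x = 0, y = 0, z = 5 + tck / 2),
                    n, seed = 5, mode = "primary")
  en <- attr(d, "energy")
  t_hat <- en$escaped / en$launched
  # beam is near-normal: path within 0.1% of the slab thickness
  t_true <- exp(-mass_attenuation("water", 60.25) * tck)
  se <- sqrt(t_true * (1 - t_true) / n)
  expect_lt(abs(t_hat - t_true), 3 * se + 1e-3 * t_true)
})

test_that("kerma in a near-vacuum phantom follows the inverse square law", {
  src <- uniform_source(tuned_120()$spectrum, 5, 15)
  ph <- build_water_phantom(c(40, 40, 40), c(0.4, 0.4, 0.3), surface_z = 15)
  ph$density[] <- 1e-6
  z <- c(17, 21, 25)
  d <- compute_dose(src, ph, data.frame(x = 0, y = 0, z = z), 2000, seed = 6)
  expect_equal(d$dose[2] / d$dose[1], (z[1] / z[2])^2, tolerance = 1e-3)
  expect_equal(d$dose[3] / d$dose[1], (z[1] / z[3])^2, tolerance = 1e-3)
})

test_that("energy is conserved history by history (analog ledger)", {
  src <- uniform_source(tuned_120()$spectrum, 5, 15)
  ph <- small_water_phantom()
  d <- compute_dose(src, ph, data.frame(x = 0, y = 0, z = 17), 5000,
                    seed = 7, mode = "collision")
  en <- attr(d, "energy")
  expect_lt(en$max_imbalance, 1e-9 * en$launched / 5000)
  expect_equal(en$deposited + en$escaped, en$launched,
               tolerance = 1e-12)
  expect_gt(en$deposited, 0)
  expect_gt(en$escaped, 0)
})

test_that("identical seeds give bit-identical results; different seeds differ", {
  src <- uniform_source(tuned_120()$spectrum, 5, 15)
  ph <- small_water_phantom()
  tl <- data.frame(x = 0, y = 0, z = c(16, 17))
  d1 <- compute_dose(src, ph, tl, 2000, seed = 11)
  d2 <- compute_dose(src, ph, tl, 2000, seed = 11)
  expect_identical(d1$dose, d2$dose)
  expect_identical(d1$stderr, d2$stderr)
  d3 <- compute_dose(src, ph, tl, 2000, seed = 12)
  expect_false(identical(d1$dose, d3$dose))
})

test_that("standard error shrinks like one over root histories", {
  src <- uniform_source(tuned_120()$spectrum, 5, 15)
  ph <- small_water_phantom()
  tl <- data.frame(x = 0, y = 0, z = 17)
  d1 <- compute_dose(src, ph, tl, 20000, seed = 13)
  d2 <- compute_dose(src, ph, tl, 80000, seed = 14)
  expect_equal(d1$stderr / d2$stderr, 2, tolerance = 0.2)
})

test_that("the three scoring routes agree on POI dose", {
  # next-event kerma (deterministic primary + point detector), analog
  # collision deposits, and track-length fluence scoring are independent
  # estimators of the same quantity
  src <- uniform_source(tuned_120()$spectrum, 5, 15)
  ph <- small_water_phantom()
  tl <- data.frame(x = 0, y = 0, z = c(16, 20))
  dk <- compute_dose(src, ph, tl, 40000, seed = 15)
  dt <- compute_dose(src, ph, tl, 150000, seed = 16, mode = "tracklength")
  dc <- compute_dose(src, ph, tl, 400000, seed = 17, mode = "collision",
                     tally_size = c(1.2, 1.2, 0.6))
  for (i in 1:2) {
    expect_lt(abs(dk$dose[i] - dt$dose[i]),
              3.5 * sqrt(dk$stderr[i]^2 + dt$stderr[i]^2) + 0.01 * dk$dose[i])
    expect_lt(abs(dk$dose[i] - dc$dose[i]),
              3.5 * sqrt(dk$stderr[i]^2 + dc$stderr[i]^2) + 0.02 * dk$dose[i])
  }
})

test_that("tallies outside the phantom and bad history counts are rejected", {
  src <- uniform_source(tuned_120()$spectrum, 5, 15)
  ph <- small_water_phantom()
  expect_error(compute_dose(src, ph, data.frame(x = 0, y = 0, z = 1),
                            2000, seed = 1), "outside")
  expect_error(compute_dose(src, ph, data.frame(x = 0, y = 0, z = 17),
                            500, seed = 1), "n_histories")
})
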