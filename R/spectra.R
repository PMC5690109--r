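# Tungsten-anode spectrum model, air-kerma HVL, and inherent-filtration tuning.

# model constants, fixed once (see methods vignette)
.TW_CONSTANT <- 1.2e6   # Thomson-Whiddington constant, keV^2 cm^2/g
.K_LINE_AMPL <- 0.08    # K characteristic amplitude (~10% fluence share at 150 kVp)
.W_K_EDGE <- 69.525     # keV
.W_K_LINES <- data.frame(
  energy = c(57.98, 59.32, 67.24, 69.07),            # Ka2, Ka1, Kb1(+3), Kb2
  intensity = c(58, 100, 33, 9) / 200)

#' Binned photon energy spectrum
#'
#' @param bin_centers Uniformly spaced bin centers in keV.
#' @param fluence Relative photons per bin, nonnegative, at least one positive;
#'   must be zero in bins at or above `kvp`.
#' @param kvp Peak tube potential (kV); the numeric maximum photon energy.
#' @return Object of class `energy_spectrum` with fields `bin_centers`,
#'   `fluence`, `kvp`, `bin_width`.
#' @export
energy_spectrum <- function(bin_centers, fluence, kvp) {
  stopifnot(length(bin_centers) == length(fluence), length(bin_centers) >= 1)
  if (length(bin_centers) > 1) {
    dw <- diff(bin_centers)
    if (max(abs(dw - dw[1])) > 1e-9 * dw[1]) {
      stop("bin centers must be uniformly spaced", call. = FALSE)
    }
    bw <- dw[1]
  } else {
    bw <- 0.5
  }
  if (bw <= 0) stop("bin width must be positive", call. = FALSE)
  if (any(fluence < 0)) stop("fluence must be nonnegative", call. = FALSE)
  if (!any(fluence > 0)) stop("spectrum has no positive bin", call. = FALSE)
  if (any(fluence[bin_centers > kvp] > 0)) {
    stop("fluence must vanish above the peak potential", call. = FALSE)
  }
  structure(list(bin_centers = bin_centers, fluence = fluence,
                 kvp = kvp, bin_width = bw),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat("Energy spectrum: ", x$kvp, " kVp, ", length(x$bin_centers),
      " bins of ", x$bin_width, " keV, mean energy ",
      round(mean_energy(x), 2), " keV\n", sep = "")
  invisible(x)
}

#' Fluence-weighted mean energy of a spectrum (keV)
#' @param spectrum An `energy_spectrum`.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$bin_centers * spectrum$fluence) / sum(spectrum$fluence)
}

#' Ordered filter stack
#'
#' @param ... Thicknesses in mm named by filter material, e.g.
#'   `filter_stack(Cu = 0.05, Al = 0.90)`; or a single named numeric vector.
#' @return Object of class `filter_stack`: data frame with `material`,
#'   `thickness_mm`.
#' @export
filter_stack <- function(...) {
  args <- list(...)
  v <- if (length(args) == 1 && is.numeric(args[[1]]) &&
           !is.null(names(args[[1]]))) {
    args[[1]]
  } else {
    unlist(args)
  }
  if (is.null(v)) v <- numeric(0)
  if (length(v) && (is.null(names(v)) || any(!nzchar(names(v))))) {
    stop("filter thicknesses must be named by material", call. = FALSE)
  }
  if (any(v < 0)) stop("filter thicknesses must be >= 0", call. = FALSE)
  for (m in names(v)) .canon_material(m)
  structure(data.frame(material = names(v), thickness_mm = unname(v),
                       stringsAsFactors = FALSE),
            class = c("filter_stack", "data.frame"))
}

#' Combine filter stacks
#' @param ... `filter_stack` objects.
#' @export
c.filter_stack <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  structure(out, class = c("filter_stack", "data.frame"))
}

#' Attenuate a spectrum through a filter stack
#'
#' Bin-wise Beer-Lambert attenuation `exp(-sum mu(E) t)` over the filters.
#'
#' @param spectrum An `energy_spectrum`.
#' @param filters A `filter_stack`.
#' @return The attenuated `energy_spectrum`.
#' @export
attenuate_spectrum <- function(spectrum, filters) {
  fl <- spectrum$fluence
  for (i in seq_len(nrow(filters))) {
    m <- filters$material[i]
    rho <- attenuation_table(m)$density_default
    fl <- fl * exp(-mass_attenuation(m, spectrum$bin_centers) * rho *
                     filters$thickness_mm[i] / 10)
  }
  energy_spectrum(spectrum$bin_centers, fl, spectrum$kvp)
}

#' Generate a tungsten-anode X-ray spectrum
#'
#' Parametric model: Kramers continuum (photon number per bin proportional to
#' `kvp/E - 1`) hardened by self-attenuation in the tungsten target along the
#' anode exit path, plus the four tungsten K characteristic lines (57.98,
#' 59.32, 67.24, 69.07 keV) when the peak potential exceeds the K edge
#' (69.525 keV), all attenuated through the inherent and added filter stacks.
#' The mean photon production depth follows a Thomson-Whiddington range and
#' the exit path divides it by the sine of the anode takeoff angle.
#'
#' @param kvp Peak tube potential, 40-160 kV.
#' @param anode_angle_deg Anode (takeoff) angle in degrees, default 30.
#' @param inherent Inherent filtration `filter_stack` (default 0.8 mm Be).
#' @param added Added filtration `filter_stack`.
#' @param bin_width Energy bin width in keV (default 0.5).
#' @return An `energy_spectrum` (relative fluence, unnormalized).
#' @export
generate_spectrum <- function(kvp, anode_angle_deg = 30,
                              inherent = filter_stack(Be = 0.8),
                              added = filter_stack(),
                              bin_width = 0.5) {
  if (kvp < 40 || kvp > 160) stop("kvp must be in [40, 160]", call. = FALSE)
  if (anode_angle_deg <= 0 || anode_angle_deg > 90) {
    stop("anode angle must be in (0, 90] degrees", call. = FALSE)
  }
  e <- seq(1 + bin_width / 2, kvp, by = bin_width)
  e <- e[e <= kvp]
  fl <- kvp / e - 1
  rho_w <- attenuation_table("W")$density_default
  # mean production depth over sin(takeoff): tungsten exit path in cm
  s_w <- kvp^2 / (2 * rho_w * .TW_CONSTANT) / sin(anode_angle_deg * pi / 180)
  fl <- fl * exp(-mass_attenuation("W", e) * rho_w * s_w)
  if (kvp > .W_K_EDGE) {
    tot <- .K_LINE_AMPL * sum(fl) * (kvp / .W_K_EDGE - 1)^1.67
    idx <- findInterval(.W_K_LINES$energy, e - bin_width / 2)
    for (i in seq_len(nrow(.W_K_LINES))) {
      fl[idx[i]] <- fl[idx[i]] + tot * .W_K_LINES$intensity[i]
    }
  }
  sp <- energy_spectrum(e, fl, kvp)
  attenuate_spectrum(sp, c(inherent, added))
}

#' Air-kerma integral of a spectrum
#'
#' The quantity the in-air ionization chamber responds to: the sum over bins
#' of fluence times the medium's mass energy-absorption coefficient times
#' energy.
#'
#' @param spectrum An `energy_spectrum`.
#' @param material_id Medium for the energy-absorption weighting
#'   (default `"air"`).
#' @return Relative kerma (arbitrary units, linear in fluence).
#' @export
kerma_integral <- function(spectrum, material_id = "air") {
  w <- mass_energy_absorption(material_id, spectrum$bin_centers)
  sum(spectrum$fluence * w * spectrum$bin_centers)
}

#' Air-kerma transmission through an attenuator
#'
#' @param spectrum An `energy_spectrum`.
#' @param thickness_mm Attenuator thickness (mm), vectorized.
#' @param attenuator_material Attenuator (default `"Al"`).
#' @return Kerma transmission relative to the open beam, per thickness.
#' @export
kerma_transmission <- function(spectrum, thickness_mm,
                               attenuator_material = "Al") {
  e <- spectrum$bin_centers
  mu <- mass_attenuation(attenuator_material, e) *
    attenuation_table(attenuator_material)$density_default
  w <- mass_energy_absorption("air", e) * e * spectrum$fluence
  k0 <- sum(w)
  vapply(thickness_mm, function(t) sum(w * exp(-mu * t / 10)) / k0,
         numeric(1))
}

#' Air-kerma half-value layer of a spectrum
#'
#' The attenuator thickness at which the air-kerma transmission integral is
#' exactly one half (or `0.5^order` relative to the previous order's level:
#' `order = 2` gives the thickness from half to quarter transmission).
#' Solved by bracketed root finding to |transmission - target| < 1e-6.
#'
#' @param spectrum An `energy_spectrum`.
#' @param attenuator_material Attenuator (default `"Al"`).
#' @param order 1 for the first HVL, 2 for the second.
#' @return Thickness in mm.
#' @export
air_kerma_hvl <- function(spectrum, attenuator_material = "Al", order = 1L) {
  stopifnot(order %in% c(1L, 2L))
  f <- function(t, target) {
    kerma_transmission(spectrum, t, attenuator_material) - target
  }
  solve_t <- function(target) {
    if (f(100, target) > 0) {
      stop("no transmission bracket within [0, 100 mm] of ",
           attenuator_material, call. = FALSE)
    }
    uniroot(f, c(0, 100), target = target, tol = 1e-10)$root
  }
  t50 <- solve_t(0.5)
  if (order == 1L) t50 else solve_t(0.25) - t50
}

#' Tune inherent filtration to match a measured HVL
#'
#' Reproduces the HVL-matching step of beam modeling: the inherent filtration
#' is treated as an unknown aluminum-equivalent thickness and adjusted by
#' monotone bisection until the generated spectrum's air-kerma HVL matches
#' the measurement.  The tuned spectrum's inherent filtration is the
#' Al-equivalent thickness alone (the nominal Be window is absorbed into it).
#'
#' @param kvp Peak tube potential (kV).
#' @param anode_angle_deg Anode angle (degrees).
#' @param added Added filtration `filter_stack`.
#' @param target_hvl_mm_al Measured first HVL to match, mm Al.
#' @param tol Convergence tolerance on HVL, mm Al (default 0.01).
#' @param bin_width Spectrum bin width, keV.
#' @return List with `thickness_mm_al` (tuned inherent Al-equivalent),
#'   `spectrum` (the tuned `energy_spectrum`) and `hvl` (its achieved HVL).
#' @export
tune_inherent_filtration <- function(kvp, anode_angle_deg = 30,
                                     added = filter_stack(),
                                     target_hvl_mm_al,
                                     tol = 0.01, bin_width = 0.5) {
  hvl_at <- function(q) {
    sp <- generate_spectrum(kvp, anode_angle_deg,
                            inherent = filter_stack(Al = q),
                            added = added, bin_width = bin_width)
    air_kerma_hvl(sp)
  }
  lo <- 0; hi <- 20
  h_lo <- hvl_at(lo); h_hi <- hvl_at(hi)
  if (target_hvl_mm_al < h_lo || target_hvl_mm_al > h_hi) {
    stop(sprintf(paste0("target HVL %.3f mm Al unreachable: inherent ",
                        "Al-equivalent bracket [%.1f, %.1f] mm spans HVL ",
                        "[%.3f, %.3f] mm Al"),
                 target_hvl_mm_al, lo, hi, h_lo, h_hi), call. = FALSE)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    h <- hvl_at(mid)
    if (abs(h - target_hvl_mm_al) < tol) break
    if (h < target_hvl_mm_al) lo <- mid else hi <- mid
  }
  sp <- generate_spectrum(kvp, anode_angle_deg,
                          inherent = filter_stack(Al = mid),
                          added = added, bin_width = bin_width)
  list(thickness_mm_al = mid, spectrum = sp, hvl = air_kerma_hvl(sp))
}

#' Import a tabulated spectrum
#'
#' Accepts an externally generated spectrum as an (energy, relative fluence)
#' table and resamples it onto the internal uniform grid by trapezoidal
#' rebinning; total fluence is conserved.
#'
#' @param energies Ascending photon energies, keV.
#' @param fluence Nonnegative relative fluence at `energies` (interpreted as
#'   a fluence density sampled at those energies).
#' @param bin_width Target uniform bin width, keV (default 0.5).
#' @param kvp Peak potential; defaults to the largest tabulated energy.
#' @return An `energy_spectrum`.
#' @export
import_spectrum <- function(energies, fluence, bin_width = 0.5, kvp = NULL) {
  if (length(energies) != length(fluence) || length(energies) < 1) {
    stop("malformed spectrum table", call. = FALSE)
  }
  if (is.unsorted(energies, strictly = TRUE)) {
    stop("energies must be strictly ascending", call. = FALSE)
  }
  if (any(fluence < 0)) stop("fluence must be nonnegative", call. = FALSE)
  if (is.null(kvp)) kvp <- max(energies)
  if (length(energies) == 1) {
    ctr <- floor(energies / bin_width) * bin_width + bin_width / 2
    return(energy_spectrum(ctr, sum(fluence), max(kvp, ctr)))
  }
  total <- sum((fluence[-1] + fluence[-length(fluence)]) / 2 * diff(energies))
  lo <- floor(min(energies) / bin_width) * bin_width
  ctr <- seq(lo + bin_width / 2, max(energies) + bin_width / 2, by = bin_width)
  ctr <- ctr[ctr - bin_width / 2 < max(energies)]
  # integrate the piecewise-linear density over each bin
  binfl <- vapply(ctr, function(cc) {
    a <- max(cc - bin_width / 2, min(energies))
    b <- min(cc + bin_width / 2, max(energies))
    if (b <= a) return(0)
    xs <- sort(unique(c(a, b, energies[energies > a & energies < b])))
    ys <- approx(energies, fluence, xs)$y
    sum((ys[-1] + ys[-length(ys)]) / 2 * diff(xs))
  }, numeric(1))
  if (total > 0 && sum(binfl) > 0) binfl <- binfl * total / sum(binfl)
  keep <- ctr <= kvp
  energy_spectrum(ctr[keep], binfl[keep], kvp)
}

#' Read / write a spectrum CSV
#'
#' Two columns `energy_keV,relative_fluence`; `#` lines are comments.
#'
#' @param path File path.
#' @param bin_width,kvp Passed to [import_spectrum()].
#' @return [read_spectrum_csv()] returns an `energy_spectrum`.
#' @export
read_spectrum_csv <- function(path, bin_width = 0.5, kvp = NULL) {
  tab <- read.table(path, sep = ",", comment.char = "#", header = FALSE,
                    col.names = c("energy_keV", "relative_fluence"))
  import_spectrum(tab$energy_keV, tab$relative_fluence,
                  bin_width = bin_width, kvp = kvp)
}

#' @rdname read_spectrum_csv
#' @param spectrum An `energy_spectrum` to write.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# energy_keV,relative_fluence (fluence density per keV)",
               sprintf("# kvp: %g", spectrum$kvp)), con)
  write.table(data.frame(spectrum$bin_centers,
                         spectrum$fluence / spectrum$bin_width), con,
              sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
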