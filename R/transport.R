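# R-side driver for the Monte Carlo engine: input marshalling, the
# deterministic primary-kerma component, and the DoseResult container.

.phantom_cxx <- function(phantom) {
  list(dims = phantom$dims, spacing = phantom$spacing,
       origin = phantom$origin, material = phantom$material - 1L,
       density = phantom$density)
}

# per-material interaction tables for the engine; fractions from the bundled
# partial cross sections, totals from the attenuation tables
.materials_cxx <- function(material_ids) {
  lapply(material_ids, function(id) {
    pp <- attenuation_partials(id)
    e <- pp$energies
    tot <- pp$photo + pp$coherent + pp$incoherent
    list(e = e,
         mu = mass_attenuation(id, e),
         muen = mass_energy_absorption(id, e),
         fphoto = pp$photo / tot, fcoh = pp$coherent / tot,
         finc = pp$incoherent / tot)
  })
}

.voxel_of <- function(phantom, p) {
  i <- floor((p - phantom$origin) / phantom$spacing)
  if (any(i < 0) || any(i >= phantom$dims)) {
    stop("point (", paste(p, collapse = ", "), ") outside the phantom",
         call. = FALSE)
  }
  1L + i[1] + phantom$dims[1] * (i[2] + phantom$dims[2] * i[3])
}

# Deterministic primary (uncollided) kerma per history at each POI: for a
# point source the unscattered fluence at a point comes from the single ray
# through it, so the component is an exact 1D quadrature over the local
# spectrum attenuated along the traced voxel path.
.primary_kerma <- function(source, phantom, tallies) {
  fm <- source$fluence
  a <- source$applicator_diameter_cm / 2
  ssd <- source$ssd_cm
  i2 <- .disk_integral(fm, a)  # normalization of the plane emission density
  pcx <- .phantom_cxx(phantom)
  out <- numeric(nrow(tallies))
  for (q in seq_len(nrow(tallies))) {
    poi <- as.numeric(tallies[q, ])
    xt <- poi[1] * ssd / poi[3]
    yt <- poi[2] * ssd / poi[3]
    if (xt^2 + yt^2 > a^2) next  # outside the sampled aperture disk
    f <- fluence_at(fm, xt, yt) / i2
    bigr <- sqrt(xt^2 + yt^2 + ssd^2)
    q_sr <- f * bigr^3 / ssd           # emissions per steradian (per history)
    r <- sqrt(sum(poi^2))
    sp <- source$spectra$spectra[[.nearest_station(source$spectra, xt)]]
    p_e <- sp$fluence / sum(sp$fluence)
    ch <- mc_ray_chords(pcx, c(0, 0, 0), poi)
    tau <- numeric(length(sp$bin_centers))
    if (length(ch$length_cm)) {
      pr <- tapply(ch$length_cm * ch$density, ch$material, sum)
      for (mi in seq_along(pr)) {
        id <- phantom$material_ids[as.integer(names(pr)[mi])]
        tau <- tau + pr[[mi]] * mass_attenuation(id, sp$bin_centers)
      }
    }
    med <- phantom$material_ids[phantom$material[.voxel_of(phantom, poi)]]
    out[q] <- q_sr / r^2 * sum(p_e * exp(-tau) *
                                 mass_energy_absorption(med, sp$bin_centers) *
                                 sp$bin_centers)
  }
  out
}

#' Monte Carlo dose at points of interest
#'
#' Transports photon histories sampled from the effective point source
#' through the voxel phantom and scores relative dose at the requested
#' points of interest (POIs).
#'
#' Scoring modes:
#' \describe{
#'   \item{`"kerma"` (default)}{Kerma-approximation scoring: the uncollided
#'     primary kerma is computed deterministically by ray-tracing the single
#'     source ray through each POI (zero variance), and the scatter kerma is
#'     estimated with a next-event point-detector contribution from every
#'     scattering event.  Efficient for POI dose at the history counts used
#'     in practice.}
#'   \item{`"collision"`}{Analog scoring: energy transferred to electrons is
#'     deposited at interaction sites inside the tally boxes; maintains an
#'     exact per-history energy ledger (deposited + escaped = launched).}
#'   \item{`"primary"`}{Histories terminate at their first interaction
#'     (attenuation-only transport, used for transmission checks).}
#'   \item{`"tracklength"`}{Chord-length fluence scoring through the tally
#'     boxes times muen/rho times E; an independent kerma estimator used to
#'     cross-check the other two routes.}
#' }
#'
#' @param source A `source_model`.
#' @param phantom A `voxel_phantom` (materials must have bundled partial
#'   cross sections: water, air).
#' @param tallies Data frame or matrix with columns `x`, `y`, `z` (cm).
#' @param n_histories Number of histories (>= 1000).
#' @param seed Integer seed; fixes both the emission sampling and the
#'   transport stream (identical inputs and seed give identical output).
#' @param mode Scoring mode, see above.
#' @param cutoff_keV Low-energy cutoff; photons below it are absorbed
#'   locally (default 5 keV).
#' @param tally_size Tally box edge lengths (cm), default
#'   `c(0.4, 0.4, 0.3)`; POI dose is the box average.
#' @param coherent Include coherent scattering (default TRUE).
#' @param nee_rmin Radius (cm) below which the point-detector estimator
#'   switches to its bounded sphere-average form.
#' @return Object of class `dose_result`: data frame `x`, `y`, `z`, `dose`,
#'   `stderr` with attributes `histories`, `seed`, `mode`, and `energy`
#'   (the per-run ledger: launched / deposited / escaped energy and the
#'   maximum per-history imbalance).
#' @export
compute_dose <- function(source, phantom, tallies, n_histories, seed,
                         mode = c("kerma", "collision", "primary",
                                  "tracklength"),
                         cutoff_keV = 5, tally_size = c(0.4, 0.4, 0.3),
                         coherent = TRUE, nee_rmin = 0.5) {
  mode <- match.arg(mode)
  tallies <- as.data.frame(tallies)
  names(tallies)[1:3] <- c("x", "y", "z")
  if (n_histories < 1000) stop("n_histories must be >= 1000", call. = FALSE)
  for (id in phantom$material_ids) attenuation_partials(id)  # validate early
  tl <- as.matrix(tallies[, c("x", "y", "z")])
  set.seed(seed)
  em <- sample_emission(source, n_histories)
  emat <- cbind(em$direction, em$energy_keV, em$weight)
  modei <- match(mode, c("collision", "kerma", "primary", "tracklength")) - 1L
  res <- mc_run(.phantom_cxx(phantom), .materials_cxx(phantom$material_ids),
                emat, tl, tally_size / 2, modei, cutoff_keV,
                as.double(seed %% 2^31), coherent, nee_rmin)
  n <- n_histories
  mean_h <- res$acc1 / n
  var_h <- pmax(0, res$acc2 / n - mean_h^2)
  se_h <- sqrt(var_h / n)
  if (mode == "kerma") {
    dose <- .primary_kerma(source, phantom, tl) + mean_h
    se <- se_h
  } else if (mode == "tracklength") {
    dose <- mean_h
    se <- se_h
  } else {
    vox <- apply(tl, 1, function(p) .voxel_of(phantom, p))
    mass <- prod(tally_size) * phantom$density[vox]
    dose <- mean_h / mass
    se <- se_h / mass
  }
  structure(data.frame(tallies[, c("x", "y", "z")], dose = dose, stderr = se),
            histories = n_histories, seed = seed, mode = mode,
            energy = list(launched = res$launched,
                          deposited = res$deposited,
                          escaped = res$escaped,
                          max_imbalance = res$max_imbalance),
            n_collisions = res$n_collisions,
            class = c("dose_result", "data.frame"))
}

#' Sample photon free-path lengths in a phantom
#'
#' Optical-depth sampling (`-log(xi)` accumulated along the voxel walk) from
#' a fixed starting state; exposes the engine's free-path sampler for
#' distribution checks.
#'
#' @param phantom A `voxel_phantom`.
#' @param position,direction Start point (cm) and unit direction.
#' @param energy_keV Photon energy.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric vector of path lengths (cm); `Inf` marks escape.
#' @export
sample_free_path <- function(phantom, position, direction, energy_keV, n,
                             seed) {
  direction <- direction / sqrt(sum(direction^2))
  mc_free_paths(.phantom_cxx(phantom), .materials_cxx(phantom$material_ids),
                position, direction, energy_keV, as.integer(n),
                as.double(seed %% 2^31))
}

#' Sample interaction outcomes at fixed energy
#'
#' Draws the interaction kind (proportional to the partial cross sections),
#' with Kahn-sampled Klein-Nishina energy/angle for incoherent events and
#' Thomson-shaped angles for coherent events.
#'
#' @param energy_keV Photon energy (above the cutoff).
#' @param material_id Transportable medium (`"water"` or `"air"`).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param coherent Include coherent scattering.
#' @return Data frame `kind` (`"photoelectric"`, `"coherent"`,
#'   `"incoherent"`), `energy_out`, `cos_theta`.
#' @export
sample_interaction <- function(energy_keV, material_id, n, seed,
                               coherent = TRUE) {
  mat <- .materials_cxx(material_id)[[1]]
  res <- mc_sample_interaction(as.integer(n), energy_keV, mat,
                               as.double(seed %% 2^31), coherent)
  data.frame(kind = c("photoelectric", "coherent",
                      "incoherent")[res$kind + 1L],
             energy_out = res$energy_out, cos_theta = res$cos_theta)
}

#' Per-voxel chord lengths of a ray
#'
#' @param phantom A `voxel_phantom`.
#' @param from,to Segment endpoints (cm).
#' @return Data frame `length_cm`, `material` (id), `density`.
#' @export
ray_chords <- function(phantom, from, to) {
  ch <- mc_ray_chords(.phantom_cxx(phantom), as.double(from), as.double(to))
  data.frame(length_cm = ch$length_cm,
             material = phantom$material_ids[ch$material],
             density = ch$density)
}

#' @export
print.dose_result <- function(x, ...) {
  cat("Dose result: ", attr(x, "histories"), " histories (seed ",
      attr(x, "seed"), ", mode ", attr(x, "mode"), ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
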