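# Synthetic-measurement generators: every pipeline stage is testable without
# an X-ray tube.  A truth source plays the role of the physical machine; the
# generators sample it the way the chamber measurements would, with
# multiplicative Gaussian reading noise (default SD 0.3%, the typical
# relative reading uncertainty of an ionization chamber).

#' Synthetic heel-effect truth source
#'
#' Builds a fully specified effective point source with a linear inline HVL
#' gradient (the spectrum hardens toward positive x, emulating the heel
#' effect on the anode side), an asymmetric inline fluence profile (reduced
#' on the anode side) and a symmetric flat-topped crossline profile whose
#' rounded edges drop by about 10% at the applicator rim.
#'
#' @param kvp Peak potential (kV).
#' @param hvl_center Central-axis first HVL to tune to (mm Al).
#' @param hvl_gradient_per_cm HVL change per cm along +x (mm Al/cm).
#' @param applicator_diameter_cm,ssd_cm Geometry.
#' @param added Added filtration `filter_stack` shared by all stations.
#' @param heel_drop Fractional fluence reduction across the aperture toward
#'   the anode side (default 0.10).
#' @param edge_drop Fractional fluence rolloff at the aperture edge
#'   (default 0.10).
#' @param station_spacing_cm Spectrum station spacing (default 3, the
#'   off-axis HVL measurement granularity).
#' @param noise_sd Reading noise the paired scan/transmission generators
#'   will use (recorded on the object; default 0.003).
#' @param seed Integer seed recorded on the object (the source itself is
#'   deterministic given the parameters).
#' @return Object of class `c("truth_source", "source_model")`: a usable
#'   `source_model` whose `$truth` field retains the generating parameters,
#'   the true per-axis fluence and the tuned per-station HVLs.
#' @export
make_heel_source <- function(kvp = 120, hvl_center = 4.5,
                             hvl_gradient_per_cm = 0,
                             applicator_diameter_cm = 15, ssd_cm = 25,
                             added = filter_stack(Al = 1.0),
                             heel_drop = 0.10, edge_drop = 0.10,
                             station_spacing_cm = 3, noise_sd = 0.003,
                             seed = 1L) {
  a <- applicator_diameter_cm / 2
  if (a <= 0 || ssd_cm <= 0) stop("aperture and SSD must be positive",
                                  call. = FALSE)
  st <- sort(unique(c(-seq(0, a, by = station_spacing_cm),
                      seq(0, a, by = station_spacing_cm), -a, a)))
  targets <- hvl_center + hvl_gradient_per_cm * st
  spectra <- lapply(seq_along(st), function(i) {
    tryCatch(
      tune_inherent_filtration(kvp, added = added,
                               target_hvl_mm_al = targets[i])$spectrum,
      error = function(e) {
        stop("unreachable HVL ", round(targets[i], 3), " mm Al at station x = ",
             st[i], " cm: ", conditionMessage(e), call. = FALSE)
      })
  })
  spacing <- if (applicator_diameter_cm <= 2) 0.25 else 0.5
  pos <- seq(-a, a, by = spacing)
  rolloff <- function(p) {
    u <- pmax(0, (abs(p) - 0.75 * a) / (0.25 * a))
    1 - edge_drop * (1 - cos(pi * pmin(u, 1))) / 2
  }
  xv <- rolloff(pos) * (1 - heel_drop * (pos + a) / (2 * a))
  xv <- xv / xv[pos == 0]
  yv <- rolloff(pos)
  src <- structure(
    list(kvp = kvp, ssd_cm = ssd_cm,
         applicator_diameter_cm = applicator_diameter_cm,
         fluence = fluence_map(pos, xv, pos, yv),
         spectra = spectrum_set(st, spectra), phi0 = 1),
    class = "source_model")
  src$truth <- list(kvp = kvp, hvl_center = hvl_center,
                    hvl_gradient_per_cm = hvl_gradient_per_cm,
                    station_positions = st, station_hvl = targets,
                    x_pos = pos, x_val = xv, y_pos = pos, y_val = yv,
                    heel_drop = heel_drop, edge_drop = edge_drop,
                    noise_sd = noise_sd, seed = as.integer(seed))
  class(src) <- c("truth_source", "source_model")
  src
}

#' Synthetic relative in-air scan
#'
#' Samples the truth source's in-air dose along one axis at the applicator
#' plane, applies multiplicative Gaussian reading noise, and normalizes to
#' the central reading -- the measurement [fluence_from_inair()] inverts.
#'
#' @param truth A `source_model` (typically a `truth_source`).
#' @param axis `"inline"` or `"crossline"`.
#' @param spacing_cm Scan spacing (default 0.25 cm for the 2 cm applicator,
#'   0.5 cm otherwise).
#' @param noise_sd Multiplicative Gaussian reading SD (default 0.003).
#' @param seed Integer seed.
#' @return An `inair_scan`.
#' @export
synthetic_inair_scan <- function(truth, axis = c("inline", "crossline"),
                                 spacing_cm = NULL, noise_sd = 0.003,
                                 seed = 1L) {
  axis <- match.arg(axis)
  a <- truth$applicator_diameter_cm / 2
  if (is.null(spacing_cm)) {
    spacing_cm <- if (truth$applicator_diameter_cm <= 2) 0.25 else 0.5
  }
  if (spacing_cm <= 0) stop("spacing must be positive", call. = FALSE)
  pos <- seq(-a, a, by = spacing_cm)
  if (!any(pos == 0)) pos <- sort(c(pos, 0))
  d <- if (axis == "inline") inair_dose_at(truth, pos, 0) else {
    inair_dose_at(truth, rep(0, length(pos)), pos)
  }
  set.seed(seed)
  readings <- d * (1 + rnorm(length(d), 0, noise_sd))
  inair_scan(axis, pos, readings, truth$applicator_diameter_cm, truth$ssd_cm)
}

#' Synthetic transmission series
#'
#' Readings proportional to the air-kerma integral of the spectrum behind
#' each attenuator thickness, with multiplicative Gaussian noise.
#'
#' @param spectrum An `energy_spectrum`.
#' @param thicknesses_mm Attenuator thicknesses including 0 (open beam).
#' @param noise_sd Multiplicative Gaussian reading SD (default 0.003).
#' @param seed Integer seed.
#' @param attenuator_material Attenuator (default `"Al"`).
#' @param position,axis Recorded measurement position.
#' @return A `transmission_series`.
#' @export
synthetic_transmission <- function(spectrum, thicknesses_mm,
                                   noise_sd = 0.003, seed = 1L,
                                   attenuator_material = "Al",
                                   position = c(0, 0),
                                   axis = NA_character_) {
  if (!any(thicknesses_mm == 0)) {
    stop("thicknesses must include 0 (open beam)", call. = FALSE)
  }
  tr <- kerma_transmission(spectrum, thicknesses_mm, attenuator_material)
  set.seed(seed)
  readings <- tr * (1 + rnorm(length(tr), 0, noise_sd))
  # keep the open-beam reading maximal under noise (it is re-measured first
  # in practice); nudge only if noise inverted the ordering
  i0 <- which(thicknesses_mm == 0)
  readings[i0] <- max(readings) * (1 + 1e-12)
  transmission_series(thicknesses_mm, readings, attenuator_material,
                      position = position, axis = axis)
}
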