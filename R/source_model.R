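# Effective point source: planar fluence maps derived from relative in-air
# dose scans, position-dependent spectra, and emission sampling.
#
# Coordinate convention: source at the origin, +z toward the phantom,
# x = inline (anode-cathode, the heel-effect axis), y = crossline; the
# applicator plane sits at z = SSD.  All positions in cm.

#' Relative in-air dose scan
#'
#' Ionization-chamber readings along one axis at the base of the applicator,
#' normalized to the central-axis value.
#'
#' @param axis `"inline"` or `"crossline"`.
#' @param positions_cm Scan positions in the applicator plane (must include 0).
#' @param readings Nonnegative readings; stored normalized to the reading
#'   at position 0.
#' @param applicator_diameter_cm Applicator (cone) base diameter.
#' @param ssd_cm Source-to-surface distance.
#' @return Object of class `inair_scan` with `relative_dose` normalized so
#'   the central value is 1.
#' @export
inair_scan <- function(axis = c("inline", "crossline"), positions_cm,
                       readings, applicator_diameter_cm, ssd_cm) {
  axis <- match.arg(axis)
  stopifnot(length(positions_cm) == length(readings))
  if (any(readings < 0)) stop("readings must be >= 0", call. = FALSE)
  i0 <- which(positions_cm == 0)
  if (length(i0) != 1) {
    stop("scan must contain position 0 exactly once", call. = FALSE)
  }
  if (readings[i0] <= 0) stop("central reading must be positive", call. = FALSE)
  o <- order(positions_cm)
  structure(list(axis = axis, positions_cm = positions_cm[o],
                 relative_dose = (readings / readings[i0])[o],
                 applicator_diameter_cm = applicator_diameter_cm,
                 ssd_cm = ssd_cm),
            class = "inair_scan")
}

#' Spectrum stations along the inline axis
#'
#' Position-dependent spectra `U(x, E)`; the spectrum is taken constant along
#' the crossline axis.  Lookup is nearest-neighbor in x, matching the
#' off-axis HVL measurement granularity.
#'
#' @param positions_cm Inline station positions.
#' @param spectra List of `energy_spectrum`, one per station.
#' @return Object of class `spectrum_set`.
#' @export
spectrum_set <- function(positions_cm, spectra) {
  stopifnot(length(positions_cm) == length(spectra), length(spectra) >= 1)
  if (!all(vapply(spectra, inherits, TRUE, "energy_spectrum"))) {
    stop("spectra must be energy_spectrum objects", call. = FALSE)
  }
  o <- order(positions_cm)
  structure(list(positions_cm = positions_cm[o], spectra = spectra[o]),
            class = "spectrum_set")
}

.nearest_station <- function(set, x) {
  vapply(x, function(xi) which.min(abs(set$positions_cm - xi)), integer(1))
}

#' Planar relative fluence map
#'
#' Separable relative photon distribution `X(x) * Y(y)` at the applicator
#' plane, normalized to 1 at the center.  Between samples the map is linear;
#' beyond the outermost sample it falls linearly to zero over one sample
#' spacing (the penumbra tail).
#'
#' @param x_positions,x_values Inline samples (must include 0).
#' @param y_positions,y_values Crossline samples (must include 0).
#' @return Object of class `fluence_map`.
#' @export
fluence_map <- function(x_positions, x_values, y_positions, y_values) {
  mk <- function(p, v, lab) {
    stopifnot(length(p) == length(v))
    if (any(v < 0)) stop(lab, " fluence values must be >= 0", call. = FALSE)
    i0 <- which(p == 0)
    if (length(i0) != 1 || v[i0] <= 0) {
      stop(lab, " samples must include position 0 with positive value",
           call. = FALSE)
    }
    o <- order(p)
    list(pos = p[o], val = (v / v[i0])[o])
  }
  xx <- mk(x_positions, x_values, "inline")
  yy <- mk(y_positions, y_values, "crossline")
  structure(list(x_pos = xx$pos, x_val = xx$val,
                 y_pos = yy$pos, y_val = yy$val),
            class = "fluence_map")
}

# evaluate one axis of a fluence map with the linear penumbra tail
.fluence_axis <- function(pos, val, q) {
  n <- length(pos)
  sp_lo <- if (n > 1) pos[2] - pos[1] else 1
  sp_hi <- if (n > 1) pos[n] - pos[n - 1] else 1
  out <- numeric(length(q))
  inside <- q >= pos[1] & q <= pos[n]
  if (any(inside)) out[inside] <- approx(pos, val, q[inside])$y
  hi <- q > pos[n] & q < pos[n] + sp_hi
  out[hi] <- val[n] * (1 - (q[hi] - pos[n]) / sp_hi)
  lo <- q < pos[1] & q > pos[1] - sp_lo
  out[lo] <- val[1] * (1 - (pos[1] - q[lo]) / sp_lo)
  out
}

# exact integral of one piecewise-linear fluence axis (with its linear
# penumbra tail) over [lo, hi]
.fluence_axis_integral <- function(pos, val, lo, hi) {
  n <- length(pos)
  sp_lo <- if (n > 1) pos[2] - pos[1] else 1
  sp_hi <- if (n > 1) pos[n] - pos[n - 1] else 1
  br <- sort(unique(c(pos, pos[1] - sp_lo, pos[n] + sp_hi, lo, hi)))
  br <- br[br >= lo & br <= hi]
  if (length(br) < 2) return(0)
  y <- .fluence_axis(pos, val, br)
  sum((y[-1] + y[-length(y)]) / 2 * diff(br))
}

# integral of X(x) Y(y) over the aperture disk of radius a
.disk_integral <- function(map, a, nx = 2001) {
  gx <- seq(-a, a, length.out = nx)
  xv <- .fluence_axis(map$x_pos, map$x_val, gx)
  ch <- sqrt(pmax(0, a^2 - gx^2))
  iy <- vapply(seq_along(gx), function(i) {
    if (ch[i] <= 0) return(0)
    .fluence_axis_integral(map$y_pos, map$y_val, -ch[i], ch[i])
  }, numeric(1))
  f <- xv * iy
  sum((f[-1] + f[-length(f)]) / 2 * diff(gx))
}

#' Evaluate a fluence map
#' @param map A `fluence_map`.
#' @param x,y Coordinates in the applicator plane (cm), vectorized.
#' @return `X(x) * Y(y)`.
#' @export
fluence_at <- function(map, x, y) {
  .fluence_axis(map$x_pos, map$x_val, x) * .fluence_axis(map$y_pos, map$y_val, y)
}

#' Derive relative fluence from an in-air dose scan
#'
#' Inverts the in-air kerma relation: the relative fluence along the scan
#' axis is the relative dose multiplied by the ratio of the central-spectrum
#' air-kerma integral to the local-spectrum air-kerma integral,
#' `X(x)/X(0) = [D(x)/D(0)] * K(U(0)) / K(U(x))`.
#' For the crossline axis the spectrum does not vary and the correction
#' factor is identically 1.
#'
#' @param scan An `inair_scan`.
#' @param spectra A `spectrum_set` (stations along inline); for a crossline
#'   scan only the central station is used.
#' @return Data frame `position_cm`, `fluence` (normalized to 1 at center).
#' @export
fluence_from_inair <- function(scan, spectra) {
  stopifnot(inherits(scan, "inair_scan"), inherits(spectra, "spectrum_set"))
  kint <- vapply(spectra$spectra, kerma_integral, numeric(1))
  i0 <- .nearest_station(spectra, 0)
  corr <- if (scan$axis == "inline") {
    kint[i0] / kint[.nearest_station(spectra, scan$positions_cm)]
  } else {
    rep(1, length(scan$positions_cm))
  }
  f <- scan$relative_dose * corr
  data.frame(position_cm = scan$positions_cm, fluence = f / f[scan$positions_cm == 0])
}

#' Build the effective point source
#'
#' Combines the per-axis fluence maps recovered from in-air scans with the
#' spectrum stations into an effective point source at the origin whose
#' emissions are back-projected through the applicator plane.
#'
#' @param kvp Peak potential of the beam (kV).
#' @param ssd_cm Source-to-surface distance (cm).
#' @param applicator_diameter_cm Cone base diameter (cm).
#' @param inline_scan,crossline_scan `inair_scan` objects spanning the
#'   aperture.
#' @param spectra A `spectrum_set` of inline stations.
#' @return Object of class `source_model` with fields `ssd_cm`,
#'   `applicator_diameter_cm`, `fluence` (a `fluence_map`), `spectra`,
#'   `kvp` and `phi0` (fixed at 1 for relative dose).
#' @export
build_source <- function(kvp, ssd_cm, applicator_diameter_cm,
                         inline_scan, crossline_scan, spectra) {
  a <- applicator_diameter_cm / 2
  for (s in list(inline_scan, crossline_scan)) {
    if (min(s$positions_cm) > -a || max(s$positions_cm) < a) {
      stop(s$axis, " scan (", min(s$positions_cm), " to ",
           max(s$positions_cm), " cm) narrower than the aperture radius ",
           a, " cm", call. = FALSE)
    }
  }
  fx <- fluence_from_inair(inline_scan, spectra)
  fy <- fluence_from_inair(crossline_scan, spectra)
  fmap <- fluence_map(fx$position_cm, fx$fluence, fy$position_cm, fy$fluence)
  structure(list(kvp = kvp, ssd_cm = ssd_cm,
                 applicator_diameter_cm = applicator_diameter_cm,
                 fluence = fmap, spectra = spectra, phi0 = 1),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat("Effective point source: ", x$kvp, " kVp, ",
      x$applicator_diameter_cm, " cm applicator at SSD ", x$ssd_cm,
      " cm, ", length(x$spectra$spectra), " spectrum station(s)\n", sep = "")
  invisible(x)
}

#' Relative in-air dose at a point of the applicator plane
#'
#' The forward model of the characterization: `X(x) Y(y)` times the air-kerma
#' integral of the local spectrum (times the calibration constant, 1 for
#' relative dose).
#'
#' @param source A `source_model`.
#' @param x,y Coordinates in the applicator plane (cm), vectorized.
#' @return Relative in-air dose (unnormalized; divide by the central value
#'   for a relative scan).
#' @export
inair_dose_at <- function(source, x, y = 0) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  fm <- source$fluence
  lim_x <- c(fm$x_pos[1] - (fm$x_pos[2] - fm$x_pos[1]),
             fm$x_pos[length(fm$x_pos)] +
               diff(fm$x_pos)[length(fm$x_pos) - 1])
  if (any(x < lim_x[1] | x > lim_x[2])) {
    stop("point outside the modeled aperture and penumbra tail",
         call. = FALSE)
  }
  kint <- vapply(source$spectra$spectra, kerma_integral, numeric(1))
  fluence_at(fm, x, y) * kint[.nearest_station(source$spectra, x)] *
    source$phi0
}

#' Sample emissions from the source
#'
#' Draws `n` photon emissions: a plane position with density proportional to
#' `X(x) Y(y)` over the aperture disk (rejection sampling), an energy from
#' the spectrum at the nearest inline station, and the unit direction from
#' the source origin through the sampled plane position.  All weights are 1.
#'
#' @param source A `source_model`.
#' @param n Number of emissions.
#' @param max_iter Rejection-sampling round cap (documented guard; the
#'   acceptance ratio is bounded below over the aperture).
#' @return List with `plane_xy` (n x 2), `direction` (n x 3 unit rows),
#'   `energy_keV`, `weight`, `station` (spectrum station index per emission).
#' @export
sample_emission <- function(source, n, max_iter = 1000L) {
  a <- source$applicator_diameter_cm / 2
  fm <- source$fluence
  gx <- seq(-a, a, length.out = 512)
  fmax <- max(outer(.fluence_axis(fm$x_pos, fm$x_val, gx),
                    .fluence_axis(fm$y_pos, fm$y_val, gx))) * 1.0001
  xs <- numeric(0); ys <- numeric(0)
  need <- n
  for (it in seq_len(max_iter)) {
    m <- max(2L * need, 100L)
    r <- a * sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
    cx <- r * cos(th); cy <- r * sin(th)
    acc <- runif(m) * fmax < fluence_at(fm, cx, cy)
    xs <- c(xs, cx[acc]); ys <- c(ys, cy[acc])
    need <- n - length(xs)
    if (need <= 0) break
  }
  if (need > 0) stop("rejection sampling failed to terminate", call. = FALSE)
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  st <- .nearest_station(source$spectra, xs)
  en <- numeric(n)
  for (k in unique(st)) {
    sp <- source$spectra$spectra[[k]]
    sel <- st == k
    bins <- sample.int(length(sp$fluence), sum(sel), replace = TRUE,
                       prob = sp$fluence)
    e <- sp$bin_centers[bins] + runif(sum(sel), -0.5, 0.5) * sp$bin_width
    en[sel] <- pmin(e, sp$kvp)
  }
  d <- cbind(xs, ys, source$ssd_cm)
  d <- d / sqrt(rowSums(d^2))
  dimnames(d) <- NULL
  list(plane_xy = cbind(x = xs, y = ys), direction = d,
       energy_keV = en, weight = rep(1, n), station = st)
}

#' Write / read a source model as JSON
#'
#' Serializes the geometry, fluence samples and per-station spectra into a
#' single structured JSON file.
#'
#' @param source A `source_model`.
#' @param path Output path.
#' @export
write_source_json <- function(source, path) {
  obj <- list(
    kvp = source$kvp, ssd_cm = source$ssd_cm,
    applicator_diameter_cm = source$applicator_diameter_cm,
    phi0 = source$phi0,
    fluence = list(x_pos = source$fluence$x_pos, x_val = source$fluence$x_val,
                   y_pos = source$fluence$y_pos, y_val = source$fluence$y_val),
    spectra = lapply(seq_along(source$spectra$positions_cm), function(i) {
      sp <- source$spectra$spectra[[i]]
      list(position_cm = source$spectra$positions_cm[i], kvp = sp$kvp,
           bin_centers = sp$bin_centers, fluence = sp$fluence)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_source_json
#' @return [read_source_json()] returns the `source_model`.
#' @export
read_source_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp_list <- obj$spectra
  if (is.data.frame(sp_list)) {
    sp_list <- lapply(seq_len(nrow(sp_list)), function(i) as.list(sp_list[i, ]))
  }
  spectra <- spectrum_set(
    vapply(sp_list, function(s) s$position_cm, numeric(1)),
    lapply(sp_list, function(s) {
      energy_spectrum(unlist(s$bin_centers), unlist(s$fluence), s$kvp)
    }))
  fmap <- fluence_map(obj$fluence$x_pos, obj$fluence$x_val,
                      obj$fluence$y_pos, obj$fluence$y_val)
  structure(list(kvp = obj$kvp, ssd_cm = obj$ssd_cm,
                 applicator_diameter_cm = obj$applicator_diameter_cm,
                 fluence = fmap, spectra = spectra, phi0 = obj$phi0),
            class = "source_model")
}
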