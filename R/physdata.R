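#' @useDynLib kvbeam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm optimize predict quantile rnorm runif sd setNames uniroot
#' @importFrom utils read.table write.table
NULL

# cache of parsed tables, keyed by canonical material id
.xs_cache <- new.env(parent = emptyenv())

# canonical ids of bundled tables
.xs_materials <- c("water", "air", "Al", "Cu", "Be", "W", "Pb",
                   "H", "C", "N", "O", "Ar")

.xs_aliases <- c(
  lead = "Pb", aluminum = "Al", aluminium = "Al", copper = "Cu",
  beryllium = "Be", tungsten = "W", hydrogen = "H", carbon = "C",
  nitrogen = "N", oxygen = "O", argon = "Ar", Water = "water", Air = "air"
)

# built-in elemental compositions (mass fractions) of the transportable media
.material_compositions <- list(
  water = c(H = 0.111894, O = 0.888106),
  air   = c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012827)
)

.canon_material <- function(material_id) {
  stopifnot(is.character(material_id), length(material_id) == 1L)
  id <- if (material_id %in% names(.xs_aliases)) {
    unname(.xs_aliases[material_id])
  } else {
    material_id
  }
  if (!id %in% .xs_materials) {
    stop("unknown material '", material_id, "'; bundled materials: ",
         paste(.xs_materials, collapse = ", "), call. = FALSE)
  }
  id
}

#' Bundled photon attenuation table for a material
#'
#' Loads (and caches) the packaged mass attenuation / mass energy-absorption
#' table for one material.  Tables are whitespace-separated text files with
#' columns `energy_keV mu_over_rho muen_over_rho` (cm^2/g) on the standard
#' NIST grid; absorption edges inside the working band appear as duplicated
#' energies so that interpolation never crosses an edge.
#'
#' @param material_id One of `"water"`, `"air"`, `"Al"`, `"Cu"`, `"Be"`,
#'   `"W"`, `"Pb"` (alias `"lead"`), or the elemental ids `"H"`, `"C"`,
#'   `"N"`, `"O"`, `"Ar"`.
#' @return An object of class `attenuation_table`: a list with `material_id`,
#'   `energies` (keV, ascending), `mu_over_rho`, `muen_over_rho` (cm^2/g) and
#'   `density_default` (g/cm^3).
#' @export
attenuation_table <- function(material_id) {
  id <- .canon_material(material_id)
  if (!is.null(.xs_cache[[id]])) return(.xs_cache[[id]])
  path <- system.file("extdata", "xsdata", paste0(id, ".txt"),
                      package = "kvbeam", mustWork = TRUE)
  lines <- readLines(path)
  dens_line <- grep("^# *density_default:", lines, value = TRUE)
  density <- as.numeric(sub("^# *density_default: *([0-9eE.+-]+).*$", "\\1",
                            dens_line[1]))
  tab <- read.table(path, comment.char = "#",
                    col.names = c("energy_keV", "mu_over_rho", "muen_over_rho"))
  if (is.unsorted(tab$energy_keV)) {
    stop("attenuation table for ", id, " has non-ascending energies")
  }
  obj <- structure(
    list(material_id = id,
         energies = tab$energy_keV,
         mu_over_rho = tab$mu_over_rho,
         muen_over_rho = tab$muen_over_rho,
         density_default = density),
    class = "attenuation_table")
  .xs_cache[[id]] <- obj
  obj
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat("Attenuation table: ", x$material_id, "\n",
      "  ", length(x$energies), " grid energies, ",
      min(x$energies), "-", max(x$energies), " keV\n",
      "  default density ", x$density_default, " g/cm^3\n", sep = "")
  invisible(x)
}

# linear interpolation in (log E, log y); exact at grid knots; duplicated
# edge energies are respected because findInterval brackets within a segment
.loginterp <- function(x, y, xout) {
  if (any(xout < x[1] | xout > x[length(x)])) {
    stop("energy outside table span [", x[1], ", ", x[length(x)], "] keV",
         call. = FALSE)
  }
  j <- findInterval(xout, x)
  res <- numeric(length(xout))
  hit <- x[j] == xout
  res[hit] <- y[j[hit]]
  if (any(!hit)) {
    nj <- j[!hit]
    t <- (log(xout[!hit]) - log(x[nj])) / (log(x[nj + 1L]) - log(x[nj]))
    res[!hit] <- exp(log(y[nj]) + t * (log(y[nj + 1L]) - log(y[nj])))
  }
  res
}

#' Mass attenuation coefficient
#'
#' Interpolated mass attenuation coefficient mu/rho (including coherent
#' scattering) for a bundled material, linear in (log E, log mu/rho).
#'
#' @param material_id Bundled material id (see [attenuation_table()]).
#' @param energy Photon energy (keV), scalar or vector, within the table span.
#' @return mu/rho in cm^2/g, same length as `energy`.
#' @export
mass_attenuation <- function(material_id, energy) {
  tab <- attenuation_table(material_id)
  .loginterp(tab$energies, tab$mu_over_rho, energy)
}

#' Mass energy-absorption coefficient
#'
#' Interpolated muen/rho, the coefficient that converts photon energy fluence
#' to absorbed dose under charged-particle equilibrium; the weighting used in
#' all air-kerma integrals.
#'
#' @inheritParams mass_attenuation
#' @return muen/rho in cm^2/g, same length as `energy`.
#' @export
mass_energy_absorption <- function(material_id, energy) {
  tab <- attenuation_table(material_id)
  .loginterp(tab$energies, tab$muen_over_rho, energy)
}

#' Mass-fraction-weighted mixture coefficient
#'
#' Applies the elemental mixture rule: the coefficient of a compound or
#' mixture is the mass-fraction-weighted sum of its components' coefficients.
#'
#' @param fractions Named numeric vector of mass fractions (names are bundled
#'   material ids); must sum to 1 within 1e-6.
#' @param energy Photon energy (keV), scalar or vector.
#' @param quantity `"mu"` for mu/rho or `"muen"` for muen/rho.
#' @return Coefficient in cm^2/g, same length as `energy`.
#' @export
mixture_coefficient <- function(fractions, energy, quantity = c("mu", "muen")) {
  quantity <- match.arg(quantity)
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("mass fractions sum to ", format(sum(fractions)),
         ", expected 1 within 1e-6", call. = FALSE)
  }
  fun <- if (quantity == "mu") mass_attenuation else mass_energy_absorption
  out <- numeric(length(energy))
  for (i in seq_along(fractions)) {
    out <- out + fractions[[i]] * fun(names(fractions)[i], energy)
  }
  out
}

#' Material definition
#'
#' A material as used by the voxel phantom: an elemental composition by mass
#' fraction plus a density.  The two media the transport engine moves photons
#' through, `"water"` and `"air"`, have built-in compositions.
#'
#' @param id Material id; if one of the built-ins, composition/density default
#'   to the bundled values.
#' @param composition Named numeric vector of elemental mass fractions
#'   (must sum to 1 within 1e-6).
#' @param density Density in g/cm^3.
#' @return An object of class `kv_material`.
#' @export
kv_material <- function(id, composition = NULL, density = NULL) {
  if (is.null(composition)) {
    cid <- .canon_material(id)
    composition <- .material_compositions[[cid]]
    if (is.null(composition)) composition <- setNames(1, cid)
  }
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("mass fractions sum to ", format(sum(composition)),
         ", expected 1 within 1e-6", call. = FALSE)
  }
  if (is.null(density)) density <- attenuation_table(id)$density_default
  structure(list(id = id, composition = composition, density = density),
            class = "kv_material")
}

#' @export
print.kv_material <- function(x, ...) {
  cat("Material ", x$id, " (", x$density, " g/cm^3): ",
      paste(sprintf("%s %.4f", names(x$composition), x$composition),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Partial interaction cross sections
#'
#' Photoelectric / coherent / incoherent mass interaction coefficients
#' (cm^2/g) for a transportable medium, summing to the bundled total at each
#' grid energy.  Used by the transport engine to draw the interaction type.
#'
#' @param material_id `"water"` or `"air"`.
#' @return List with `energies`, `photo`, `coherent`, `incoherent` (cm^2/g).
#' @export
attenuation_partials <- function(material_id) {
  id <- .canon_material(material_id)
  key <- paste0("partials_", id)
  if (!is.null(.xs_cache[[key]])) return(.xs_cache[[key]])
  path <- system.file("extdata", "xsdata", paste0("partials_", id, ".txt"),
                      package = "kvbeam")
  if (!nzchar(path)) {
    stop("no partial cross-section table bundled for '", id, "'",
         call. = FALSE)
  }
  tab <- read.table(path, comment.char = "#",
                    col.names = c("energy_keV", "photo", "coherent",
                                  "incoherent"))
  obj <- list(energies = tab$energy_keV, photo = tab$photo,
              coherent = tab$coherent, incoherent = tab$incoherent)
  .xs_cache[[key]] <- obj
  obj
}

#' Klein-Nishina total cross section per electron
#'
#' Analytic integrated Klein-Nishina cross section for a free electron, in
#' cm^2 per electron.  Used to construct incoherent partial coefficients and
#' as the normalization of the sampled Compton angular distribution.
#'
#' @param energy Photon energy in keV (vectorized).
#' @return Cross section in cm^2.
#' @export
klein_nishina_total <- function(energy) {
  r_e <- 2.8179403262e-13 # classical electron radius, cm
  k <- energy / 510.99895
  term1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  term2 <- log(1 + 2 * k) / (2 * k)
  term3 <- -(1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * r_e^2 * (term1 + term2 + term3)
}
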