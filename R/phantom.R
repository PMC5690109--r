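# Voxelized phantoms: construction, HU -> material/density mapping, raw+JSON
# sidecar I/O.
#
# Indexing is 0-based in the file format and C++ engine; world coordinates
# are voxel-center based: voxel (i, j, k) has center
# origin + ((i, j, k) + 0.5) * spacing.  The phantom surface plane is placed
# at z = SSD by the builders.

#' Voxelized phantom
#'
#' @param dims Integer grid dimensions `(nx, ny, nz)`, all >= 1.
#' @param spacing Voxel size `(dx, dy, dz)` in cm, all > 0.
#' @param origin Grid corner (cm): world position of the (0,0,0) voxel corner.
#' @param material Character array (or scalar) of material ids per voxel,
#'   x-fastest order; or an integer array indexing into `material_ids`.
#' @param density Numeric array (or scalar) of densities, g/cm^3.
#' @param material_ids Levels for integer `material`.
#' @return Object of class `voxel_phantom`: `dims`, `spacing`, `origin`,
#'   `material` (integer, 1-based into `material_ids`), `material_ids`,
#'   `density`.
#' @export
voxel_phantom <- function(dims, spacing, origin, material, density,
                          material_ids = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), length(spacing) == 3,
            all(spacing > 0), length(origin) == 3)
  nvox <- prod(dims)
  if (is.character(material)) {
    material_ids <- unique(material)
    material <- match(material, material_ids)
  }
  if (is.null(material_ids)) stop("material_ids required for integer material",
                                  call. = FALSE)
  material <- rep_len(as.integer(material), nvox)
  if (anyNA(material) || any(material < 1) || any(material > length(material_ids))) {
    stop("every voxel must have a mapped material", call. = FALSE)
  }
  density <- rep_len(as.double(density), nvox)
  if (any(density <= 0)) stop("densities must be positive", call. = FALSE)
  structure(list(dims = dims, spacing = as.double(spacing),
                 origin = as.double(origin), material = material,
                 material_ids = material_ids, density = density),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  ext <- x$dims * x$spacing
  cat("Voxel phantom: ", paste(x$dims, collapse = "x"), " voxels (",
      format(prod(x$dims), big.mark = ","), "), ",
      paste(x$spacing, collapse = "x"), " cm -> extent ",
      paste(round(ext, 2), collapse = " x "), " cm\n  materials: ",
      paste(x$material_ids, collapse = ", "), "; origin (",
      paste(round(x$origin, 3), collapse = ", "), ") cm\n", sep = "")
  invisible(x)
}

#' Physical extent of a phantom (cm per axis)
#' @param phantom A `voxel_phantom`.
#' @export
phantom_extent <- function(phantom) phantom$dims * phantom$spacing

#' Build a homogeneous water phantom
#'
#' All voxels water at 1.0 g/cm^3, centered on the beam axis with its top
#' surface at `surface_z` (the SSD).
#'
#' @param dims Grid dimensions `(nx, ny, nz)`.
#' @param voxel_size Voxel size `(dx, dy, dz)` in cm.
#' @param surface_z World z of the phantom surface (cm), default 15.
#' @return A `voxel_phantom`.
#' @export
build_water_phantom <- function(dims = c(103, 103, 108),
                                voxel_size = c(0.4, 0.4, 0.3),
                                surface_z = 15) {
  if (any(dims < 1) || any(voxel_size <= 0)) {
    stop("dims must be >= 1 and voxel sizes > 0", call. = FALSE)
  }
  origin <- c(-dims[1] * voxel_size[1] / 2, -dims[2] * voxel_size[2] / 2,
              surface_z)
  voxel_phantom(dims, voxel_size, origin, material = 1L, density = 1.0,
                material_ids = "water")
}

#' The reference water phantom grids
#'
#' The full measurement-scale grid is 512 x 512 x 108 voxels of
#' 0.081 x 0.081 x 0.30 cm^3 (28,311,552 voxels, 32.4 cm deep); the default
#' dose-engine grid downsamples the transverse plane to 103 x 103 voxels of
#' 0.4 cm, which point-of-interest tallies do not resolve beyond.
#'
#' @param full If `TRUE`, build the full 512 x 512 x 108 grid.
#' @param surface_z World z of the phantom surface (cm).
#' @return A `voxel_phantom`.
#' @export
reference_water_phantom <- function(full = FALSE, surface_z = 15) {
  if (full) {
    build_water_phantom(c(512, 512, 108), c(0.081, 0.081, 0.30), surface_z)
  } else {
    build_water_phantom(c(103, 103, 108), c(0.4, 0.4, 0.3), surface_z)
  }
}

#' Hounsfield-unit mapping
#'
#' Ordered, non-overlapping HU intervals mapped to a material and a density
#' ramp (linear in HU between the interval endpoints).
#'
#' @param hu_lo,hu_hi Interval bounds (intervals are `[lo, hi)`, the last is
#'   closed).
#' @param material Material id per interval.
#' @param density_lo,density_hi Densities at the interval endpoints.
#' @return Object of class `hu_mapping`.
#' @export
hu_mapping <- function(hu_lo, hu_hi, material, density_lo, density_hi) {
  n <- length(hu_lo)
  stopifnot(length(hu_hi) == n, length(material) == n,
            length(density_lo) == n, length(density_hi) == n)
  o <- order(hu_lo)
  m <- data.frame(hu_lo = hu_lo[o], hu_hi = hu_hi[o], material = material[o],
                  density_lo = density_lo[o], density_hi = density_hi[o])
  if (any(m$hu_hi <= m$hu_lo) ||
      (n > 1 && any(m$hu_lo[-1] < m$hu_hi[-n]))) {
    stop("HU intervals must be non-overlapping and increasing", call. = FALSE)
  }
  structure(m, class = c("hu_mapping", "data.frame"))
}

#' The standard two-bin air/water HU mapping
#'
#' HU below -300 map to air (density ramp from vacuum-like to 0.3 g/cm^3);
#' HU from -300 map to water with the usual linear density ramp
#' (1.0 g/cm^3 at HU 0).
#'
#' @export
standard_hu_mapping <- function() {
  hu_mapping(hu_lo = c(-1100, -300), hu_hi = c(-300, 2000),
             material = c("air", "water"),
             density_lo = c(0.001205 * 0.1, 0.7), density_hi = c(0.7, 3.0))
}

#' Map an HU volume to a voxel phantom
#'
#' @param hu Numeric array of Hounsfield units (x-fastest, length
#'   `prod(dims)`).
#' @param dims,spacing,origin Grid geometry (see [voxel_phantom()]).
#' @param mapping A `hu_mapping` covering every HU value present.
#' @return A `voxel_phantom`.
#' @export
apply_hu_mapping <- function(hu, dims, spacing, origin,
                             mapping = standard_hu_mapping()) {
  hu <- as.double(hu)
  stopifnot(length(hu) == prod(dims))
  idx <- findInterval(hu, mapping$hu_lo)
  bad <- idx == 0 | hu > mapping$hu_hi[pmin(idx, nrow(mapping))] |
    (idx > 0 & hu >= mapping$hu_hi[pmax(idx, 1L)] & hu > mapping$hu_hi[nrow(mapping)])
  if (any(bad)) {
    stop("HU value ", hu[which(bad)[1]], " at voxel index ",
         which(bad)[1] - 1L, " (0-based) not covered by the mapping",
         call. = FALSE)
  }
  frac <- (hu - mapping$hu_lo[idx]) /
    (mapping$hu_hi[idx] - mapping$hu_lo[idx])
  dens <- mapping$density_lo[idx] +
    frac * (mapping$density_hi[idx] - mapping$density_lo[idx])
  mats <- unique(mapping$material)
  voxel_phantom(dims, spacing, origin,
                material = match(mapping$material[idx], mats),
                density = dens, material_ids = mats)
}

#' Write / read a phantom volume (raw + JSON sidecar)
#'
#' The density and material arrays are stored as little-endian raw binaries
#' (float64 density, int32 material index, z-fastest order) next to a JSON
#' sidecar header recording dims, spacing, origin, dtype, material ids and
#' expected byte counts.  Round trips are bit-exact.
#'
#' @param phantom A `voxel_phantom`.
#' @param path Base path; writes `path.json`, `path.density.raw`,
#'   `path.material.raw`.
#' @export
write_volume <- function(phantom, path) {
  hdr <- list(dims = phantom$dims, spacing = phantom$spacing,
              origin = phantom$origin, material_ids = phantom$material_ids,
              axis_order = "z-fastest", endian = "little",
              density_dtype = "float64", material_dtype = "int32",
              density_bytes = prod(phantom$dims) * 8L,
              material_bytes = prod(phantom$dims) * 4L)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  # file order is z-fastest; in-memory arrays are x-fastest
  perm <- function(v) as.vector(aperm(array(v, phantom$dims), c(3, 2, 1)))
  con <- file(paste0(path, ".density.raw"), "wb")
  writeBin(perm(phantom$density), con, size = 8, endian = "little")
  close(con)
  con <- file(paste0(path, ".material.raw"), "wb")
  writeBin(as.integer(perm(phantom$material)), con, size = 4,
           endian = "little")
  close(con)
  invisible(path)
}

#' @rdname write_volume
#' @return [read_volume()] returns the `voxel_phantom`.
#' @export
read_volume <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(hdr$dims)
  nvox <- prod(dims)
  rd <- function(suffix, what, size, expected) {
    f <- paste0(path, suffix)
    actual <- file.info(f)$size
    if (is.na(actual) || actual != expected) {
      stop("size mismatch in ", f, ": expected ", expected, " bytes, found ",
           ifelse(is.na(actual), 0, actual), call. = FALSE)
    }
    con <- file(f, "rb")
    on.exit(close(con))
    readBin(con, what, n = nvox, size = size, endian = "little")
  }
  dens <- rd(".density.raw", "double", 8, hdr$density_bytes)
  mat <- rd(".material.raw", "integer", 4, hdr$material_bytes)
  unperm <- function(v) {
    as.vector(aperm(array(v, rev(dims)), c(3, 2, 1)))
  }
  voxel_phantom(dims, hdr$spacing, hdr$origin,
                material = unperm(mat), density = unperm(dens),
                material_ids = hdr$material_ids)
}
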