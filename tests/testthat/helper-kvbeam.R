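# shared builders, memoised so expensive objects are made once per run
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# the Table 1 beam descriptions (nominal tube data)
table1_beams <- list(
  `80`  = list(kvp = 80,  added = c(Al = 1.70),            hvl = 2.06),
  `120` = list(kvp = 120, added = c(Cu = 0.05, Al = 0.90), hvl = 4.18),
  `140` = list(kvp = 140, added = c(Cu = 0.20, Al = 1.15), hvl = 7.14),
  `150` = list(kvp = 150, added = c(Cu = 1.00, Al = 1.20), hvl = 13.40))

nominal_spectrum <- function(kvp) {
  b <- table1_beams[[as.character(kvp)]]
  memo(paste0("nom", kvp),
       generate_spectrum(b$kvp, added = filter_stack(b$added)))
}

tuned_120 <- function() {
  memo("tuned120",
       tune_inherent_filtration(120,
                                added = filter_stack(Cu = 0.05, Al = 0.90),
                                target_hvl_mm_al = 4.18))
}

# monoenergetic spectrum at an arbitrary energy (single 0.5 keV bin)
mono_spectrum <- function(energy_keV) {
  ctr <- floor(energy_keV / 0.5) * 0.5 + 0.25
  energy_spectrum(c(ctr - 0.5, ctr, ctr + 0.5), c(0, 1, 0), kvp = ctr + 0.25)
}

# uniform-fluence source: flat scans, single spectrum
uniform_source <- function(spectrum, applicator_diameter_cm = 5,
                           ssd_cm = 15) {
  a <- applicator_diameter_cm / 2
  pos <- if (a <= 1) seq(-a, a, length.out = 9) else seq(-a, a, by = 0.5)
  mk <- function(ax) inair_scan(ax, pos, rep(1, length(pos)),
                                applicator_diameter_cm, ssd_cm)
  build_source(spectrum$kvp, ssd_cm, applicator_diameter_cm,
               mk("inline"), mk("crossline"), spectrum_set(0, list(spectrum)))
}

# near-pencil monoenergetic beam aimed down the axis
pencil_source <- function(energy_keV, ssd_cm = 5, aperture_cm = 0.2) {
  uniform_source(mono_spectrum(energy_keV), aperture_cm, ssd_cm)
}

small_water_phantom <- function(surface_z = 15, depth_cm = 18,
                                half_width_cm = 8, voxel = c(0.4, 0.4, 0.3)) {
  build_water_phantom(c(ceiling(2 * half_width_cm / voxel[1]),
                        ceiling(2 * half_width_cm / voxel[2]),
                        ceiling(depth_cm / voxel[3])),
                      voxel, surface_z = surface_z)
}

mu_water <- function(energy_keV) mass_attenuation("water", energy_keV) * 1.0
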