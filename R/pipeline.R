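# End-to-end pipeline driver: characterize -> compute -> analyze, with a
# declarative config, stage logging and deterministic outputs.

#' Read in-air scan CSV
#'
#' Columns `position_cm,axis,reading`; `#` comments.  Returns one
#' `inair_scan` per axis present.
#'
#' @param path CSV path.
#' @param applicator_diameter_cm,ssd_cm Geometry attached to the scans.
#' @return Named list of `inair_scan` (by axis).
#' @export
read_inair_csv <- function(path, applicator_diameter_cm, ssd_cm) {
  tab <- read.table(path, sep = ",", comment.char = "#", header = TRUE)
  if (!all(c("position_cm", "axis", "reading") %in% names(tab))) {
    stop("in-air CSV needs columns position_cm,axis,reading", call. = FALSE)
  }
  lapply(split(tab, tab$axis), function(g) {
    inair_scan(g$axis[1], g$position_cm, g$reading,
               applicator_diameter_cm, ssd_cm)
  })
}

#' Write an in-air scan CSV
#' @param scans List of `inair_scan`.
#' @param path Output path.
#' @export
write_inair_csv <- function(scans, path) {
  rows <- do.call(rbind, lapply(scans, function(s) {
    data.frame(position_cm = s$positions_cm, axis = s$axis,
               reading = s$relative_dose)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# position_cm,axis,reading", con)
  write.table(rows, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The study conditions of the default run: a 120 kVp beam (0.05 mm Cu +
#' 0.90 mm Al added filtration) on the 5 cm applicator at SSD 15 cm, dose
#' computed in the water phantom at 1-10 cm depths.
#'
#' @param out_dir Output directory for pipeline artifacts.
#' @return Nested config list (beam / geometry / engine / analysis / paths).
#' @export
default_config <- function(out_dir = tempfile("kvbeam_run_")) {
  list(beam = list(kvp = 120, added = c(Cu = 0.05, Al = 0.90),
                   anode_angle_deg = 30, target_hvl_mm_al = 4.18),
       geometry = list(ssd_cm = 15, applicator_diameter_cm = 5),
       engine = list(histories = 20000L, seed = 1L, cutoff_keV = 5),
       analysis = list(normalization = "surface", poly_order = 3,
                       depths_cm = 1:10, profile_depth_cm = 1),
       paths = list(out_dir = out_dir))
}

.cfg_hash <- function(config) {
  config$paths$out_dir <- NULL  # volatile; identical runs hash identically
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 9973)) %%
            .Machine$integer.max)
}

#' Run the characterize -> compute -> analyze pipeline
#'
#' Stages: (1) load or synthesize the in-air scans and per-station spectra
#' (HVL-tuned from transmission series when measured data are given,
#' fixture-generated otherwise); (2) build the effective point source;
#' (3) build the water phantom and compute central-axis and profile doses;
#' (4) extract the PDD and profile and write all artifacts.  Outputs embed
#' the config hash and seed; identical config and seed give byte-identical
#' outputs.
#'
#' @param config Config list as from [default_config()]; `config$paths` may
#'   name `inline_scan` / `crossline_scan` / `transmission` CSVs (validated
#'   before any computation) and `reference_pdd` for a comparison stage.
#' @param quiet Suppress INFO logging to the console (the log file is
#'   always written).
#' @return Invisible list of output paths plus the key in-memory results
#'   (`source`, `pdd`, `profile`, `stats`).
#' @export
run_pipeline <- function(config = default_config(), quiet = TRUE) {
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- file(log_path, "w")
  on.exit(close(logf))
  info <- function(...) {
    msg <- paste0("INFO ", ...)
    writeLines(msg, logf)
    if (!quiet) message(msg)
  }

  # -- validation: every referenced input path must exist up front
  for (f in c("inline_scan", "crossline_scan", "transmission",
              "reference_pdd")) {
    p <- config$paths[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop("validation: missing input path for '", f, "': ", p,
           call. = FALSE)
    }
  }
  seed <- as.integer(config$engine$seed)
  hash <- .cfg_hash(config)
  info("config hash ", hash, ", seed ", seed)
  jsonlite::write_json(c(config, list(config_hash = hash)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  beam <- config$beam; geom <- config$geometry
  added <- filter_stack(beam$added)
  info("beam ", beam$kvp, " kVp, anode angle ", beam$anode_angle_deg,
       " deg (tube nominal), added filtration ",
       paste(beam$added, names(beam$added), collapse = " + "), " mm")

  # -- stage 1: scans and spectra
  if (!is.null(config$paths$inline_scan)) {
    scans <- c(read_inair_csv(config$paths$inline_scan,
                              geom$applicator_diameter_cm, geom$ssd_cm),
               read_inair_csv(config$paths$crossline_scan,
                              geom$applicator_diameter_cm, geom$ssd_cm))
    inline <- scans$inline; crossline <- scans$crossline
    info("scans loaded from ", config$paths$inline_scan, " / ",
         config$paths$crossline_scan)
  } else {
    truth <- make_heel_source(beam$kvp, hvl_center = beam$target_hvl_mm_al,
                              applicator_diameter_cm =
                                geom$applicator_diameter_cm,
                              ssd_cm = geom$ssd_cm, added = added,
                              seed = seed)
    inline <- synthetic_inair_scan(truth, "inline", noise_sd = 0,
                                   seed = seed)
    crossline <- synthetic_inair_scan(truth, "crossline", noise_sd = 0,
                                      seed = seed + 1L)
    info("scans synthesized from fixture truth source (noise 0)")
  }
  if (!is.null(config$paths$transmission)) {
    series <- read_transmission_csv(config$paths$transmission)
    hmap <- hvl_map(series)
    spectra <- spectrum_set(hmap$position_cm,
                            lapply(hmap$hvl_mm, function(h) {
                              tune_inherent_filtration(beam$kvp,
                                beam$anode_angle_deg, added, h)$spectrum
                            }))
    info("spectra tuned to ", nrow(hmap), " measured HVL stations")
  } else {
    tuned <- tune_inherent_filtration(beam$kvp, beam$anode_angle_deg, added,
                                      beam$target_hvl_mm_al)
    spectra <- spectrum_set(0, list(tuned$spectrum))
    info("single-station spectrum tuned to HVL ",
         round(tuned$hvl, 3), " mm Al (inherent Al-equivalent ",
         round(tuned$thickness_mm_al, 3), " mm)")
  }

  # -- stage 2: source model
  source <- build_source(beam$kvp, geom$ssd_cm, geom$applicator_diameter_cm,
                         inline, crossline, spectra)
  src_path <- file.path(out_dir, "source.json")
  write_source_json(source, src_path)
  info("source model written: ", src_path)

  # -- stage 3: phantom and dose
  phantom <- build_water_phantom(surface_z = geom$ssd_cm)
  info("water phantom ", paste(phantom$dims, collapse = "x"),
       " voxels (default engine grid)")
  depths <- config$analysis$depths_cm
  tallies <- data.frame(x = 0, y = 0, z = geom$ssd_cm + depths)
  dose <- compute_dose(source, phantom, tallies,
                       n_histories = config$engine$histories, seed = seed,
                       cutoff_keV = config$engine$cutoff_keV)
  dose_path <- file.path(out_dir, "dose.csv")
  write_curve_csv(data.frame(x = dose$x, y = dose$y, z = dose$z,
                             dose_rel = dose$dose, stderr_rel = dose$stderr),
                  dose_path,
                  comments = c(paste("config_hash:", hash),
                               paste("seed:", seed)))
  info("dose computed: ", config$engine$histories, " histories")

  # -- stage 4: analysis
  pdd <- extract_pdd(dose, geom$ssd_cm,
                     normalize = config$analysis$normalization,
                     order = config$analysis$poly_order)
  pdd_path <- file.path(out_dir, "pdd.csv")
  write_curve_csv(pdd, pdd_path, comments = c(paste("config_hash:", hash),
                                              paste("seed:", seed)))
  pdepth <- config$analysis$profile_depth_cm
  a <- geom$applicator_diameter_cm / 2
  z <- geom$ssd_cm + pdepth
  xoff <- seq(-floor(a), floor(a), by = 1)
  prof_dose <- compute_dose(source, phantom,
                            data.frame(x = xoff * z / geom$ssd_cm, y = 0,
                                       z = z),
                            n_histories = config$engine$histories,
                            seed = seed + 1L,
                            cutoff_keV = config$engine$cutoff_keV)
  profile <- profile_curve(xoff * z / geom$ssd_cm, prof_dose$dose, pdepth)
  prof_path <- file.path(out_dir, "profile.csv")
  write_curve_csv(profile, prof_path,
                  comments = c(paste("config_hash:", hash),
                               paste("seed:", seed)))
  stats <- list(config_hash = hash, seed = seed,
                surface_pdd = 100,
                pdd_at_5cm = pdd$pdd[match(5, pdd$depth_cm)],
                hvl_station_count = length(spectra$spectra))
  if (!is.null(config$paths$reference_pdd)) {
    ref <- read_reference_pdd(config$paths$reference_pdd)
    cs <- compare_to_reference(pdd, ref,
                               technique = list(kvp = beam$kvp,
                                                ssd_cm = geom$ssd_cm))
    stats$reference_comparison <- cs[c("min", "max", "mean_abs", "sd_abs")]
    info("reference comparison: mean |PD| ", round(cs$mean_abs, 2), "%")
  }
  stats_path <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, stats_path, auto_unbox = TRUE, digits = NA)
  info("analysis written: ", pdd_path, ", ", prof_path, ", ", stats_path)

  invisible(list(out_dir = out_dir, source_json = src_path,
                 dose_csv = dose_path, pdd_csv = pdd_path,
                 profile_csv = prof_path, stats_json = stats_path,
                 log = log_path, source = source, pdd = pdd,
                 profile = profile, stats = stats))
}
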