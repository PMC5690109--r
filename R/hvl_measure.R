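# HVL determination from measured transmission series by three-point
# semilogarithmic interpolation, for central-axis and off-axis positions.

#' Transmission series
#'
#' One attenuation measurement series: detector readings versus added
#' attenuator thickness at a fixed position in the applicator plane.  The
#' open-beam reading (thickness 0) must be present and maximal.
#'
#' @param thicknesses_mm Attenuator thicknesses in mm, distinct, including 0.
#' @param readings Detector readings (arbitrary units), same length.
#' @param attenuator_material Attenuator id (default `"Al"`).
#' @param position Position `(x, y)` in cm in the applicator plane.
#' @param axis Optional axis label, `"inline"` or `"crossline"`.
#' @return Object of class `transmission_series`.
#' @export
transmission_series <- function(thicknesses_mm, readings,
                                attenuator_material = "Al",
                                position = c(0, 0), axis = NA_character_) {
  stopifnot(length(thicknesses_mm) == length(readings))
  if (anyDuplicated(thicknesses_mm)) {
    stop("thicknesses must be distinct", call. = FALSE)
  }
  if (any(thicknesses_mm < 0)) stop("thicknesses must be >= 0", call. = FALSE)
  if (!any(thicknesses_mm == 0)) {
    stop("open-beam reading (thickness 0) is required", call. = FALSE)
  }
  open <- readings[thicknesses_mm == 0]
  if (open < max(readings)) {
    stop("open-beam reading must be maximal", call. = FALSE)
  }
  o <- order(thicknesses_mm)
  structure(list(thicknesses_mm = thicknesses_mm[o], readings = readings[o],
                 attenuator_material = attenuator_material,
                 position = position, axis = axis),
            class = "transmission_series")
}

#' @export
print.transmission_series <- function(x, ...) {
  cat("Transmission series (", x$attenuator_material, "): ",
      length(x$thicknesses_mm), " readings, thicknesses ",
      min(x$thicknesses_mm), "-", max(x$thicknesses_mm), " mm at (",
      x$position[1], ", ", x$position[2], ") cm\n", sep = "")
  invisible(x)
}

#' HVL by three-point semilogarithmic interpolation
#'
#' Fits a quadratic in (thickness, log relative transmission) through the
#' three measured thicknesses whose transmissions lie closest to 50%, and
#' returns the thickness at which the fitted curve crosses one half.  Exact
#' for monoenergetic (purely exponential) data; second-order accurate for
#' hardened polyenergetic beams.  When four points straddle 50%
#' symmetrically, the set with two points below 50% is preferred (the
#' hardened curve is shallower at depth).
#'
#' @param series A `transmission_series` with at least three nonzero
#'   thicknesses and transmissions bracketing 0.5.
#' @param selection `"nearest"` (default) picks the three points with
#'   transmission closest to 0.5; `"two-below"` forces one point above and
#'   two below 50%.
#' @return HVL in mm of the series' attenuator.
#' @export
hvl_three_point <- function(series, selection = c("nearest", "two-below")) {
  selection <- match.arg(selection)
  open <- series$readings[series$thicknesses_mm == 0]
  nz <- series$thicknesses_mm > 0
  t <- series$thicknesses_mm[nz]
  tr <- series$readings[nz] / open
  if (length(t) < 3) {
    stop("need at least three nonzero-thickness readings", call. = FALSE)
  }
  if (any(diff(tr) >= 0)) {
    stop("non-monotone transmission readings (measurement error?)",
         call. = FALSE)
  }
  if (!any(tr > 0.5) || !any(tr < 0.5)) {
    stop("readings do not bracket 50% transmission", call. = FALSE)
  }
  d <- abs(tr - 0.5)
  if (selection == "nearest") {
    o <- order(d, -t)   # ties broken toward larger thickness (two below 50%)
    idx <- sort(o[1:3])
  } else {
    above <- which(tr > 0.5)
    below <- which(tr < 0.5)
    if (length(below) < 2) {
      idx <- sort(c(above[order(d[above])][1:2], below[order(d[below])][1]))
    } else {
      idx <- sort(c(above[which.max(t[above])],
                    below[order(d[below])][1:2]))
    }
  }
  tt <- t[idx]; ly <- log(tr[idx])
  fit <- lm(ly ~ tt + I(tt^2))
  cf <- coef(fit)
  a <- cf[[3]]; b <- cf[[2]]; cc <- cf[[1]] - log(0.5)
  roots <- if (abs(a) < 1e-14) {
    -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("quadratic fit has no 50% crossing", call. = FALSE)
    (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  }
  # bracketing interval around the 50% crossing of the data
  iu <- max(which(tr > 0.5)); il <- min(which(tr < 0.5))
  lo <- t[iu]; hi <- t[il]
  ok <- roots >= lo - 1e-9 & roots <= hi + 1e-9
  if (!any(ok)) {
    stop("interpolated HVL falls outside the bracketing thicknesses",
         call. = FALSE)
  }
  r <- roots[ok]
  r[which.min(abs(r - (lo + hi) / 2))]
}

#' Off-axis HVL map
#'
#' Applies [hvl_three_point()] to a list of transmission series measured at
#' positions along one axis.
#'
#' @param series_list List of `transmission_series` sharing axis and
#'   attenuator; positions are taken from the coordinate that varies.
#' @param ... Passed to [hvl_three_point()].
#' @return Object of class `hvl_map`: data frame with `position_cm`,
#'   `hvl_mm`, plus attributes `axis` and `attenuator_material`.
#' @export
hvl_map <- function(series_list, ...) {
  stopifnot(length(series_list) >= 1)
  att <- unique(vapply(series_list, `[[`, "", "attenuator_material"))
  ax <- unique(vapply(series_list, `[[`, "", "axis"))
  ax <- ax[!is.na(ax)]
  if (length(att) != 1 || length(ax) > 1) {
    stop("all series must share axis and attenuator", call. = FALSE)
  }
  coord <- if (length(ax) == 1 && identical(ax, "crossline")) 2L else 1L
  pos <- vapply(series_list, function(s) s$position[coord], numeric(1))
  hvl <- vapply(seq_along(series_list), function(i) {
    tryCatch(hvl_three_point(series_list[[i]], ...),
             error = function(e) {
               stop("position ", pos[i], " cm: ", conditionMessage(e),
                    call. = FALSE)
             })
  }, numeric(1))
  o <- order(pos)
  structure(data.frame(position_cm = pos[o], hvl_mm = hvl[o]),
            axis = if (length(ax)) ax else NA_character_,
            attenuator_material = att,
            class = c("hvl_map", "data.frame"))
}

#' Read transmission series from CSV
#'
#' Columns `thickness_mm,reading[,position_cm,axis]`; `#` comments.  Rows
#' sharing (position, axis) form one series.
#'
#' @param path CSV path.
#' @param attenuator_material Attenuator id for all series.
#' @return A list of `transmission_series`.
#' @export
read_transmission_csv <- function(path, attenuator_material = "Al") {
  tab <- read.table(path, sep = ",", comment.char = "#", header = TRUE)
  if (!all(c("thickness_mm", "reading") %in% names(tab))) {
    stop("transmission CSV needs columns thickness_mm,reading", call. = FALSE)
  }
  if (!"position_cm" %in% names(tab)) tab$position_cm <- 0
  if (!"axis" %in% names(tab)) tab$axis <- "inline"
  keys <- interaction(tab$position_cm, tab$axis, drop = TRUE)
  lapply(split(tab, keys), function(g) {
    pos <- if (identical(g$axis[1], "crossline")) {
      c(0, g$position_cm[1])
    } else {
      c(g$position_cm[1], 0)
    }
    transmission_series(g$thickness_mm, g$reading, attenuator_material,
                        position = pos, axis = g$axis[1])
  })
}
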