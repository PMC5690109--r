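# Depth-dose and profile analysis: PDD extraction, surface extrapolation,
# percent-difference statistics, reference comparison.

#' Percentage depth-dose curve
#'
#' @param depth_cm Ascending depths below the surface (cm).
#' @param pdd Relative dose in percent (100 at the normalization point).
#' @param stderr Optional per-point standard error (same percent scale).
#' @param normalization `"surface"` (100 at extrapolated depth 0) or
#'   `"shallowest"` (100 at the first depth).
#' @return Object of class `depth_dose_curve` (data frame `depth_cm`, `pdd`,
#'   `stderr`).
#' @export
depth_dose_curve <- function(depth_cm, pdd, stderr = NA_real_,
                             normalization = "surface") {
  if (is.unsorted(depth_cm, strictly = TRUE)) {
    stop("depths must be strictly ascending", call. = FALSE)
  }
  structure(data.frame(depth_cm = depth_cm, pdd = pdd,
                       stderr = rep_len(stderr, length(depth_cm))),
            normalization = normalization,
            class = c("depth_dose_curve", "data.frame"))
}

#' Extract a PDD from a dose result
#'
#' Takes central-axis tallies of a `dose_result`, converts tally z to depth
#' (`z - SSD`) and normalizes to 100 at the surface value obtained by
#' polynomial extrapolation (kV beams peak at or near the surface), or at
#' the shallowest depth.
#'
#' @param dose_result A `dose_result` with on-axis tallies.
#' @param ssd_cm Source-to-surface distance (phantom surface z).
#' @param normalize `"surface"` or `"shallowest"`.
#' @param order,k Surface-extrapolation polynomial order and number of
#'   shallowest points (defaults 3 and 5).
#' @param axis_tol Maximum |x|, |y| for a tally to count as on-axis (cm).
#' @return A `depth_dose_curve`.
#' @export
extract_pdd <- function(dose_result, ssd_cm,
                        normalize = c("surface", "shallowest"),
                        order = 3, k = 5, axis_tol = 1e-6) {
  normalize <- match.arg(normalize)
  on_axis <- abs(dose_result$x) <= axis_tol & abs(dose_result$y) <= axis_tol
  if (!all(on_axis)) stop("tallies not on the central axis", call. = FALSE)
  if (nrow(dose_result) < 2) stop("need >= 2 axial tallies", call. = FALSE)
  o <- order(dose_result$z)
  depth <- dose_result$z[o] - ssd_cm
  dose <- dose_result$dose[o]
  se <- dose_result$stderr[o]
  d0 <- if (normalize == "surface") {
    surface_extrapolate(data.frame(depth_cm = depth, pdd = dose),
                        order = min(order, length(depth) - 1),
                        k = min(k, length(depth)))
  } else {
    dose[1]
  }
  if (d0 <= 0) stop("non-positive normalization value", call. = FALSE)
  depth_dose_curve(depth, 100 * dose / d0, 100 * se / d0,
                   normalization = normalize)
}

#' Polynomial surface extrapolation
#'
#' Least-squares polynomial of the stated order through the shallowest `k`
#' points of a depth-dose curve, evaluated at depth 0; the standard way to
#' recover the surface value a scanning chamber cannot measure.
#'
#' @param curve A `depth_dose_curve` or data frame with `depth_cm` and a dose
#'   column (`pdd`).
#' @param order Polynomial order (>= 1).
#' @param k Number of shallowest points used (default 5).
#' @return Extrapolated dose at depth 0.
#' @export
surface_extrapolate <- function(curve, order = 3, k = 5) {
  d <- curve$depth_cm
  y <- curve$pdd
  o <- order(d)
  use <- o[seq_len(min(k, length(d)))]
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (length(use) < order + 1) {
    stop("underdetermined fit: ", length(use), " points for order ", order,
         call. = FALSE)
  }
  fit <- lm(y[use] ~ poly(d[use], order, raw = TRUE))
  unname(coef(fit)[1])  # raw polynomial evaluated at depth 0
}

#' Off-axis profile curve
#'
#' @param position_cm Off-axis positions (must include 0).
#' @param value Relative dose normalized to 100 on the central axis.
#' @param depth_cm Measurement depth.
#' @param axis `"inline"` or `"crossline"`.
#' @return Object of class `profile_curve` (data frame).
#' @export
profile_curve <- function(position_cm, value, depth_cm,
                          axis = "inline") {
  i0 <- which(position_cm == 0)
  if (length(i0) != 1) stop("profile must include position 0", call. = FALSE)
  o <- order(position_cm)
  structure(data.frame(position_cm = position_cm[o],
                       value = (100 * value / value[i0])[o]),
            depth_cm = depth_cm, axis = axis,
            class = c("profile_curve", "data.frame"))
}

#' Percent-difference statistics between two curves
#'
#' Computes the signed per-point percent difference `100 (a - b) / b` after
#' linear interpolation of the second curve onto the first curve's
#' abscissae, and summarizes it the way beam-model validations are reported:
#' the signed range plus the mean and standard deviation of the absolute
#' differences (signed summaries are also kept).
#'
#' @param a,b Data frames whose first column is the abscissa and second the
#'   value (e.g. `depth_dose_curve`s), or numeric vectors on matched
#'   abscissae.
#' @param x_a,x_b Optional abscissae when `a`, `b` are bare vectors.
#' @param x_window Optional half-width: keep only points with |x| <=
#'   `x_window`.  For profile comparisons this excludes the high-gradient
#'   region beyond the aperture edge (pass the aperture radius).
#' @return Object of class `comparison_stats`: list with `per_point` (data
#'   frame `x`, `a`, `b`, `pd`), `min`, `max`, `mean_abs`, `sd_abs`,
#'   `mean_signed`, `sd_signed`, `n`.
#' @export
percent_difference_stats <- function(a, b, x_a = NULL, x_b = NULL,
                                     x_window = NULL) {
  get_xy <- function(v, x) {
    if (is.data.frame(v)) list(x = v[[1]], y = v[[2]])
    else if (!is.null(x)) list(x = x, y = v)
    else list(x = seq_along(v), y = v)
  }
  aa <- get_xy(a, x_a); bb <- get_xy(b, x_b)
  keep <- aa$x >= min(bb$x) & aa$x <= max(bb$x)
  if (!is.null(x_window)) keep <- keep & abs(aa$x) <= x_window
  if (!any(keep)) stop("no overlapping abscissa range", call. = FALSE)
  x <- aa$x[keep]; ya <- aa$y[keep]
  yb <- if (length(bb$x) > 1) approx(bb$x, bb$y, x)$y else rep(bb$y, length(x))
  if (any(yb == 0)) stop("zero reference value", call. = FALSE)
  pd <- 100 * (ya - yb) / yb
  structure(list(per_point = data.frame(x = x, a = ya, b = yb, pd = pd),
                 min = min(pd), max = max(pd),
                 mean_abs = mean(abs(pd)), sd_abs = sd(abs(pd)),
                 mean_signed = mean(pd), sd_signed = sd(pd),
                 n = length(pd)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf(paste0("Percent differences over %d points: range [%.2f, ",
                     "%.2f]%%, mean |PD| %.2f%%, SD |PD| %.2f%%\n"),
              x$n, x$min, x$max, x$mean_abs,
              ifelse(is.na(x$sd_abs), 0, x$sd_abs)))
  invisible(x)
}

#' Combine uncertainty components in quadrature
#'
#' @param components Nonnegative percent uncertainties.
#' @param digits Decimals in the reported value (default 1, the convention
#'   for stated measurement uncertainties).
#' @return Total percent uncertainty.
#' @export
quadrature_uncertainty <- function(components, digits = 1) {
  if (any(components < 0)) stop("components must be >= 0", call. = FALSE)
  round(sqrt(sum(components^2)), digits)
}

#' Compare a PDD against a reference table
#'
#' Matches the measurement technique metadata (kVp, SSD, field/applicator)
#' before comparing; a mismatched technique is refused with both techniques
#' printed rather than silently compared.  HVL is reported but matched to
#' the nearest available beam quality, as reference compendia tabulate by
#' quality.
#'
#' @param curve A `depth_dose_curve`.
#' @param reference A reference table as returned by
#'   [read_reference_pdd()]: data frame `depth_cm`, `pdd` with metadata
#'   attributes `kvp`, `hvl_mm_al`, `ssd_cm`, `field`.
#' @param technique List with the curve's own `kvp`, `ssd_cm`, `field`
#'   (and optionally `hvl_mm_al`).
#' @return A `comparison_stats`.
#' @export
compare_to_reference <- function(curve, reference, technique) {
  meta <- attributes(reference)[c("kvp", "ssd_cm", "field")]
  for (f in names(meta)) {
    if (!is.null(technique[[f]]) && !is.null(meta[[f]]) &&
        !isTRUE(all.equal(technique[[f]], meta[[f]]))) {
      stop("technique mismatch on ", f, ": curve has ",
           format(technique[[f]]), ", reference has ", format(meta[[f]]),
           "\n  curve technique:     ",
           paste(names(technique), unlist(technique), sep = "=",
                 collapse = ", "),
           "\n  reference technique: ",
           paste(names(meta), unlist(meta), sep = "=", collapse = ", "),
           call. = FALSE)
    }
  }
  percent_difference_stats(curve, reference)
}

#' Read a reference PDD CSV
#'
#' Columns `depth_cm,pdd` with `#`-prefixed metadata header lines of the
#' form `# key: value` for `kvp`, `hvl_mm_al`, `ssd_cm`, `field`.
#'
#' @param path CSV path.
#' @return Data frame `depth_cm`, `pdd` with metadata attributes.
#' @export
read_reference_pdd <- function(path) {
  lines <- readLines(path)
  meta <- list()
  for (l in grep("^#", lines, value = TRUE)) {
    m <- regmatches(l, regexec("^# *([A-Za-z_]+) *: *(.*)$", l))[[1]]
    if (length(m) == 3) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(v)) trimws(m[3]) else v
    }
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], sep = ",",
                    header = TRUE)
  names(tab)[1:2] <- c("depth_cm", "pdd")
  for (f in names(meta)) attr(tab, f) <- meta[[f]]
  tab
}

#' Write a curve CSV
#' @param curve A data frame (`depth_dose_curve`, `profile_curve`, ...).
#' @param path Output path.
#' @param comments Optional `#` header lines (without the `#`).
#' @export
write_curve_csv <- function(curve, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  write.table(as.data.frame(curve), con, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
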