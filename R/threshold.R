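#' Lesion measurements
#'
#' Builds a table of hydrogel lesion measurements for threshold calibration.
#' Each replicate records either the total lesion width along the
#' inter-electrode axis (`extent_mm`, the caliper-like readout) or the
#' planar lesion area on the equatorial plane (`area_mm2`) - exactly one of
#' the two.
#'
#' @param replicate_id identifiers.
#' @param extent_mm lesion extents (mm) or `NA`.
#' @param area_mm2 lesion areas (mm^2) or `NA`.
#' @return Data frame of class `lesion_measurements`.
#' @export
lesion_measurements <- function(replicate_id, extent_mm = NA_real_,
                                area_mm2 = NA_real_) {
  df <- data.frame(replicate_id = replicate_id, extent_mm = extent_mm,
                   area_mm2 = area_mm2)
  bad <- is.na(df$extent_mm) == is.na(df$area_mm2)
  if (any(bad))
    stop("each replicate must have exactly one of extent_mm or area_mm2")
  class(df) <- c("lesion_measurements", "data.frame")
  df
}

#' Invert a lesion measurement to a lethal field threshold
#'
#' Maps an observed lesion boundary back to the electric-field level that
#' produced it, using a field map solved for the same electrode
#' configuration. In extent mode the threshold is the field magnitude on the
#' inter-electrode axis at distance `extent/2` from the midpoint (the lesion
#' is symmetric about the midpoint, so its half-width locates the live/dead
#' boundary). In area mode it is the isocontour level whose enclosed area on
#' the equatorial plane equals the measured lesion area.
#'
#' @param field a `field_map` solved for the measurement's configuration.
#' @param extent_mm lesion extent in mm (extent mode).
#' @param area_mm2 lesion area in mm^2 (area mode).
#' @return Threshold estimate in V/cm.
#' @export
invert_lesion <- function(field, extent_mm = NULL, area_mm2 = NULL) {
  stopifnot(inherits(field, "field_map"))
  if (is.null(extent_mm) == is.null(area_mm2))
    stop("supply exactly one of extent_mm or area_mm2")
  if (!is.null(extent_mm)) {
    stopifnot(extent_mm > 0)
    prof <- field_axis_profile(field)
    half <- extent_mm / 2
    if (half > max(prof$x))
      stop("lesion extent reaches beyond the field map")
    approx(prof$x, prof$magnitude, xout = half)$y
  } else {
    stopifnot(area_mm2 > 0)
    k0 <- (field$dims[3] + 1) / 2
    plane <- field$magnitude[, , k0]
    npx <- round(area_mm2 / field$h^2)
    if (npx < 1 || npx > length(plane))
      stop("lesion area outside the attainable isocontour areas of this map")
    # level whose superlevel set covers npx voxels: the npx-th largest value
    sort(as.numeric(plane), decreasing = TRUE)[npx]
  }
}

#' Estimate the lethal electric-field threshold from replicate lesions
#'
#' Inverts each replicate lesion against its field map and aggregates the
#' per-replicate thresholds into mean, sample SD, minimum, maximum, and n -
#' the summary conventionally reported as "mean +/- SD [min to max] V/cm".
#'
#' @param measurements a [lesion_measurements()] table.
#' @param fields a single `field_map` (shared by all replicates, the usual
#'   case for a fixed calibration geometry) or a list with one map per
#'   replicate.
#' @return An object of class `threshold_estimate` with fields `mean`, `sd`,
#'   `minimum`, `maximum`, `n`, and the per-replicate `thresholds`.
#' @export
#' @examples
#' \donttest{
#' el <- electrode_config(spacing = 4, applied_voltage = 1400,
#'                        exposed_length = Inf)
#' dom <- build_domain(0, 1, el, resolution = 0.2, extent = c(16, 16, 1))
#' fm <- solve_field(dom)
#' m <- lesion_measurements(1:3, extent_mm = c(7.2, 7.5, 7.0))
#' estimate_threshold(m, fm)
#' }
estimate_threshold <- function(measurements, fields) {
  stopifnot(nrow(measurements) >= 1)
  if (inherits(fields, "field_map"))
    fields <- rep(list(fields), nrow(measurements))
  stopifnot(length(fields) == nrow(measurements))
  thresholds <- vapply(seq_len(nrow(measurements)), function(i) {
    th <- tryCatch({
      if (!is.na(measurements$extent_mm[i]))
        invert_lesion(fields[[i]], extent_mm = measurements$extent_mm[i])
      else
        invert_lesion(fields[[i]], area_mm2 = measurements$area_mm2[i])
    }, error = function(e) {
      stop(sprintf("replicate %s: %s", measurements$replicate_id[i],
                   conditionMessage(e)), call. = FALSE)
    })
    th
  }, numeric(1))
  n <- length(thresholds)
  structure(list(mean = mean(thresholds),
                 sd = if (n > 1) sd(thresholds) else 0,
                 minimum = min(thresholds), maximum = max(thresholds),
                 n = n, thresholds = thresholds),
            class = "threshold_estimate")
}

#' Construct a threshold summary directly
#'
#' Wraps published or externally calibrated threshold statistics (e.g. a
#' lethal threshold of 525 +/- 77, range 442 to 613 V/cm) in the same class
#' returned by [estimate_threshold()], so they can seed the dose planner.
#'
#' @param mean,sd,minimum,maximum summary statistics in V/cm.
#' @param n number of replicates behind the summary.
#' @return A `threshold_estimate`.
#' @export
threshold_estimate <- function(mean, sd, minimum, maximum, n = NA_integer_) {
  stopifnot(sd >= 0, minimum <= mean, mean <= maximum)
  structure(list(mean = mean, sd = sd, minimum = minimum, maximum = maximum,
                 n = n, thresholds = NULL),
            class = "threshold_estimate")
}

#' @export
format.threshold_estimate <- function(x, ...) {
  sprintf("%.0f ± %.0f [%.0f to %.0f] V/cm",
          x$mean, x$sd, x$minimum, x$maximum)
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat("Lethal electric-field threshold:", format(x))
  if (!is.na(x$n)) cat(sprintf(" (n = %d)", x$n))
  cat("\n")
  invisible(x)
}
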