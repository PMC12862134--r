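#' Two-channel fluorescence frame
#'
#' One timepoint of a spheroid time-lapse: the green (eGFP, tumor viability)
#' and deep-red (CellTracker, CAR T-cell) channels plus acquisition
#' metadata.
#'
#' @param well_id well identifier.
#' @param timepoint_h hours post-treatment (>= 0).
#' @param green,deepred numeric intensity matrices of identical shape,
#'   non-negative.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return An object of class `fluor_frame`.
#' @export
fluor_frame <- function(well_id, timepoint_h, green, deepred = NULL,
                        pixel_size_um = 10) {
  stopifnot(is.matrix(green), all(green >= 0), timepoint_h >= 0,
            pixel_size_um > 0)
  if (is.null(deepred)) deepred <- array(0, dim = dim(green))
  stopifnot(identical(dim(green), dim(deepred)), all(deepred >= 0))
  structure(list(well_id = well_id, timepoint_h = timepoint_h,
                 green = green, deepred = deepred,
                 pixel_size_um = pixel_size_um),
            class = "fluor_frame")
}

#' Segment a tumor spheroid from the green channel
#'
#' Automatic replacement for a hand-drawn region of interest: Gaussian
#' smoothing, Otsu thresholding on the rescaled image, retention of the
#' largest connected component, and hole filling. Rescaling to `[0, 1]`
#' before thresholding makes the segmentation invariant to affine intensity
#' changes. A constant (featureless) image yields an empty mask flagged via
#' `attr(mask, "empty")`, not an error.
#'
#' @param green numeric intensity matrix.
#' @param smooth_sigma Gaussian smoothing SD in pixels.
#' @return Logical mask matrix with attribute `empty`.
#' @export
segment_mcts <- function(green, smooth_sigma = 2) {
  stopifnot(is.matrix(green), length(green) > 0)
  rng <- range(green)
  if (diff(rng) == 0) {
    mask <- matrix(FALSE, nrow(green), ncol(green))
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  img <- (green - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  bin <- EBImage::imageData(sm) > th
  if (!any(bin)) {
    mask <- matrix(FALSE, nrow(green), ncol(green))
    attr(mask, "empty") <- TRUE
    return(mask)
  }
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labs <- EBImage::imageData(lab)
  counts <- tabulate(labs[labs > 0])
  keep <- which.max(counts)
  mask <- labs == keep
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  mask <- EBImage::imageData(mask) > 0
  attr(mask, "empty") <- FALSE
  mask
}

#' Per-frame spheroid metrics
#'
#' Computes the background-subtracted channel intensities and the spheroid
#' area for one frame. The background region is everything outside a 10-px
#' dilation of the mask, keeping the peri-spheroid halo out of the
#' background estimate. The deep-red channel is measured inside the same
#' green-derived mask, which is what makes its net intensity an
#' infiltration readout.
#'
#' @param frame a [fluor_frame()].
#' @param mask logical mask (defaults to [segment_mcts()] of the green
#'   channel).
#' @param halo_px dilation radius excluded from the background region.
#' @return One-row data frame: `well_id`, `timepoint_h`, `area_mm2`,
#'   `mean_green_inside`, `mean_green_background`, `net_green`,
#'   `net_deepred`, `empty`.
#' @export
frame_metrics <- function(frame, mask = segment_mcts(frame$green),
                          halo_px = 10) {
  stopifnot(inherits(frame, "fluor_frame"),
            identical(dim(mask), dim(frame$green)))
  empty <- !any(mask)
  if (empty) {
    return(data.frame(well_id = frame$well_id, timepoint_h = frame$timepoint_h,
                      area_mm2 = 0, mean_green_inside = NA_real_,
                      mean_green_background = NA_real_,
                      net_green = NA_real_, net_deepred = NA_real_,
                      empty = TRUE))
  }
  area_mm2 <- sum(mask) * (frame$pixel_size_um / 1000)^2
  brush <- EBImage::makeBrush(2 * halo_px + 1, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
  bg_region <- !dil
  if (!any(bg_region)) bg_region <- !mask  # tiny images: fall back to complement
  g_in <- mean(frame$green[mask]); g_bg <- mean(frame$green[bg_region])
  r_in <- mean(frame$deepred[mask]); r_bg <- mean(frame$deepred[bg_region])
  data.frame(well_id = frame$well_id, timepoint_h = frame$timepoint_h,
             area_mm2 = area_mm2, mean_green_inside = g_in,
             mean_green_background = g_bg, net_green = g_in - g_bg,
             net_deepred = r_in - r_bg, empty = FALSE)
}

#' Normalize a longitudinal spheroid track to baseline
#'
#' Divides each frame's net green intensity and area by the spheroid's own
#' pre-treatment (first timepoint) values, giving the normalized-GFP and
#' normalized-area curves used to follow viability and swelling over time.
#'
#' @param metrics data frame of per-frame metrics (rows ordered or
#'   orderable by `timepoint_h`), as rbind-ed from [frame_metrics()].
#' @param baseline optional externally supplied baseline row (e.g. a
#'   control well at time zero) as a one-row data frame with `net_green`
#'   and `area_mm2`; defaults to the track's own first timepoint.
#' @return The metrics ordered by time with columns `normalized_green` and
#'   `normalized_area` appended; class `spheroid_track`.
#' @export
normalize_track <- function(metrics, baseline = NULL) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 2)
  metrics <- metrics[order(metrics$timepoint_h), ]
  if (anyDuplicated(metrics$timepoint_h))
    stop("timepoints must be strictly increasing")
  if (is.null(baseline)) baseline <- metrics[1, ]
  if (is.na(baseline$net_green) || baseline$net_green <= 0)
    stop("baseline net green intensity must be positive")
  if (baseline$area_mm2 <= 0) stop("baseline area must be positive")
  metrics$normalized_green <- metrics$net_green / baseline$net_green
  metrics$normalized_area <- metrics$area_mm2 / baseline$area_mm2
  class(metrics) <- c("spheroid_track", "data.frame")
  metrics
}

#' @export
plot.spheroid_track <- function(x, ...) {
  plot(x$timepoint_h, x$normalized_green, type = "b", pch = 19,
       xlab = "time post-treatment (h)", ylab = "fraction of baseline",
       ylim = range(0, x$normalized_green, x$normalized_area, na.rm = TRUE),
       ...)
  lines(x$timepoint_h, x$normalized_area, type = "b", pch = 1, lty = 2)
  legend("topright", c("net green (viability)", "area"),
         pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' XTT absorbance normalization
#'
#' Applies the reference-wavelength correction to XTT plate readings
#' (specific absorbance at 475 nm minus the 660-nm reference) and expresses
#' each well as fold of the control mean. An alternative ratio-style
#' correction (A475 / A660) is available via `mode = "ratio"`.
#'
#' @param a475,a660 absorbance readings (>= 0), vectorized.
#' @param control_mean mean normalized absorbance of the control wells
#'   (> 0).
#' @param well_id optional identifiers.
#' @param mode `"subtract"` (default, conventional) or `"ratio"`.
#' @return Data frame with `normalized_absorbance` and `fold_of_control`.
#' @export
#' @examples
#' xtt_normalize(0.9, 0.1, control_mean = 0.8)
xtt_normalize <- function(a475, a660, control_mean,
                          well_id = seq_along(a475),
                          mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  if (any(a475 < 0) || any(a660 < 0)) stop("absorbances must be non-negative")
  if (control_mean <= 0) stop("control mean must be positive")
  norm <- if (mode == "subtract") a475 - a660 else a475 / a660
  data.frame(well_id = well_id, a475 = a475, a660 = a660,
             normalized_absorbance = norm,
             fold_of_control = norm / control_mean)
}
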