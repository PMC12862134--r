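#' Pulse delivery scheme
#'
#' Describes the pulse train applied during irreversible electroporation (IRE).
#' The conventional clinical scheme is 90 bursts of 90-microsecond pulses
#' delivered at 1 Hz. The scheme is carried as treatment metadata; the
#' quasi-static field solver does not simulate the transient waveform.
#'
#' @param pulse_count number of pulses (> 0).
#' @param pulse_width_us pulse width in microseconds (> 0).
#' @param repetition_rate_hz pulse repetition rate in Hz (> 0).
#' @return An object of class `pulse_scheme`.
#' @export
#' @examples
#' pulse_scheme() # the conventional 90 x 90 us @ 1 Hz scheme
pulse_scheme <- function(pulse_count = 90, pulse_width_us = 90,
                         repetition_rate_hz = 1) {
  stopifnot(pulse_count > 0, pulse_width_us > 0, repetition_rate_hz > 0)
  structure(list(pulse_count = pulse_count, pulse_width_us = pulse_width_us,
                 repetition_rate_hz = repetition_rate_hz),
            class = "pulse_scheme")
}

#' @export
print.pulse_scheme <- function(x, ...) {
  cat(sprintf("Pulse scheme: %d x %g-us pulses at %g Hz\n",
              x$pulse_count, x$pulse_width_us, x$repetition_rate_hz))
  invisible(x)
}

#' Electrode configuration
#'
#' Geometry and drive voltage for either a two-needle electrode pair (the
#' in vivo configuration) or parallel plates (the cuvette / 4-well plate
#' configuration used for uniform-field exposures).
#'
#' @param mode `"needle_pair"` or `"parallel_plate"`.
#' @param spacing center-to-center needle spacing, or plate gap, in mm.
#' @param applied_voltage applied potential difference in V (>= 0).
#' @param electrode_radius needle radius in mm (needle mode only).
#' @param exposed_length conductive (exposed) needle length in mm. `Inf`
#'   means the needles penetrate the whole domain depth. `NULL` defers the
#'   default (the tumor diameter) to [build_domain()].
#' @param pulses a [pulse_scheme()] carried as metadata.
#' @return An object of class `electrode_config`.
#' @export
#' @examples
#' electrode_config(spacing = 5, applied_voltage = 1250)
electrode_config <- function(mode = c("needle_pair", "parallel_plate"),
                             spacing, applied_voltage,
                             electrode_radius = 0.5,
                             exposed_length = NULL,
                             pulses = pulse_scheme()) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(spacing), length(spacing) == 1, spacing > 0,
            is.numeric(applied_voltage), length(applied_voltage) == 1,
            applied_voltage >= 0)
  if (mode == "needle_pair") {
    stopifnot(electrode_radius > 0)
    if (spacing <= 2 * electrode_radius)
      stop("needle spacing must exceed the electrode diameter (overlapping electrodes)")
  }
  structure(list(mode = mode, spacing = spacing,
                 electrode_radius = electrode_radius,
                 exposed_length = exposed_length,
                 applied_voltage = applied_voltage,
                 pulses = pulses),
            class = "electrode_config")
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf("Electrode configuration (%s)\n", x$mode))
  cat(sprintf("  spacing: %g mm, applied voltage: %g V (%g V/cm)\n",
              x$spacing, x$applied_voltage,
              voltage_distance_ratio(x)))
  if (x$mode == "needle_pair")
    cat(sprintf("  needle radius: %g mm, exposed length: %s mm\n",
                x$electrode_radius,
                if (is.null(x$exposed_length)) "tumor diameter"
                else format(x$exposed_length)))
  invisible(x)
}

#' Voltage-to-distance ratio of an electrode configuration
#'
#' The clinical IRE dose parameter: applied voltage divided by electrode
#' spacing, in V/cm.
#'
#' @param electrodes an [electrode_config()].
#' @return Ratio in V/cm.
#' @export
voltage_distance_ratio <- function(electrodes) {
  electrodes$applied_voltage / (electrodes$spacing / 10)
}

# label codes used throughout the grid machinery
.LAB_BACKGROUND <- 0L
.LAB_TUMOR <- 1L
.LAB_PLUS <- 2L
.LAB_MINUS <- 3L

#' Build a voxelized tissue/electrode domain
#'
#' Rasterizes a spherical tumor embedded in homogeneous background tissue
#' with a two-needle electrode pair (or parallel plates) on a regular
#' Cartesian grid, ready for [solve_field()]. The tumor is centered on the
#' inter-electrode midpoint; needle axes run along z, perpendicular to the
#' tumor equatorial (xy) plane, with the exposed length centered on the
#' equator. `tumor_diameter = 0` builds a uniform phantom (e.g. a collagen
#' hydrogel) with no tumor compartment.
#'
#' @param tumor_diameter tumor diameter in mm (0 for a uniform phantom).
#' @param conductivities either a length-2 vector `c(tumor, background)` in
#'   S/m, or a single value for a homogeneous medium.
#' @param electrodes an [electrode_config()].
#' @param resolution voxel edge length in mm; must not exceed the electrode
#'   radius so the needles are resolved.
#' @param extent physical domain edge lengths in mm: a scalar or length-3
#'   vector (x, y, z). Defaults to four electrode spacings in every axis, a
#'   margin at which the insulating outer boundary has negligible effect.
#'   The x and y extents must always be at least 4x the spacing; the z
#'   extent may be smaller only when the needles penetrate the full depth
#'   (`exposed_length = Inf`), in which case the solution is z-invariant.
#' @return An object of class `tissue_domain`: label grid, conductivity
#'   grid, voxel size, and axis coordinates (mm, centered on the midpoint).
#' @export
#' @examples
#' el <- electrode_config(spacing = 5, applied_voltage = 1250)
#' dom <- build_domain(6, c(0.2, 0.1), el, resolution = 0.5)
#' table(dom$labels)
build_domain <- function(tumor_diameter, conductivities, electrodes,
                         resolution, extent = NULL) {
  stopifnot(inherits(electrodes, "electrode_config"),
            is.numeric(resolution), resolution > 0,
            is.numeric(tumor_diameter), tumor_diameter >= 0)
  if (length(conductivities) == 1) conductivities <- rep(conductivities, 2)
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  sp <- electrodes$spacing
  a <- electrodes$electrode_radius
  needle <- electrodes$mode == "needle_pair"
  if (needle && resolution > a)
    stop("resolution coarser than the electrode radius; needles would not be resolved")

  exposed <- electrodes$exposed_length
  if (needle && is.null(exposed))
    exposed <- if (tumor_diameter > 0) tumor_diameter else Inf
  penetrating <- needle && is.infinite(exposed)

  if (is.null(extent)) {
    extent <- if (needle) rep(4 * sp, 3) else c(2 * sp, 2 * sp, 2 * sp)
  }
  if (length(extent) == 1) extent <- rep(extent, 3)
  stopifnot(length(extent) == 3, all(extent > 0))
  if (needle) {
    if (any(extent[1:2] < 4 * sp))
      stop("domain x/y extent must be at least 4x the electrode spacing")
    if (!penetrating && extent[3] < 4 * sp)
      stop("domain z extent must be at least 4x the spacing unless needles penetrate the full depth")
  }
  if (tumor_diameter >= min(extent))
    stop("tumor larger than domain")
  if (needle && sp / 2 + a >= extent[1] / 2)
    stop("electrodes outside domain")
  if (needle && !penetrating && exposed > extent[3])
    stop("electrode exposed length exceeds domain depth")

  h <- resolution
  n_axis <- function(e) {
    ni <- ceiling(e / h)
    if (ni %% 2 == 0) ni <- ni + 1L
    as.integer(ni)
  }
  dims <- vapply(extent, n_axis, integer(1))
  coords <- lapply(dims, function(ni) (seq_len(ni) - (ni + 1) / 2) * h)
  names(coords) <- c("x", "y", "z")

  cx <- coords$x; cy <- coords$y; cz <- coords$z
  labels <- array(.LAB_BACKGROUND, dim = dims)

  if (tumor_diameter > 0) {
    r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    labels[r2 <= (tumor_diameter / 2)^2] <- .LAB_TUMOR
  }

  if (needle) {
    zin <- if (penetrating) rep(TRUE, dims[3]) else abs(cz) <= exposed / 2
    in_plus <- outer((cx - sp / 2)^2, cy^2, `+`) <= a^2
    in_minus <- outer((cx + sp / 2)^2, cy^2, `+`) <= a^2
    if (!any(in_plus) || !any(in_minus))
      stop("electrode rasterization produced an empty voxel set; refine the resolution")
    for (k in which(zin)) {
      lk <- labels[, , k]
      lk[in_plus] <- .LAB_PLUS
      lk[in_minus] <- .LAB_MINUS
      labels[, , k] <- lk
    }
  } else {
    labels[cx >= sp / 2, , ] <- .LAB_PLUS
    labels[cx <= -sp / 2, , ] <- .LAB_MINUS
    if (!any(labels == .LAB_PLUS) || !any(labels == .LAB_MINUS))
      stop("plate rasterization produced an empty voxel set; enlarge the domain")
  }

  sigma <- array(conductivities[2], dim = dims)
  sigma[labels == .LAB_TUMOR] <- conductivities[1]
  # electrode voxels are perfect conductors as far as the exterior problem is
  # concerned; their conductivity value only enters the face averages at the
  # electrode surface, where a high value pins the surface close to the
  # Dirichlet potential
  sigma[labels >= .LAB_PLUS] <- max(conductivities) * 1e3

  structure(list(labels = labels, sigma = sigma, h = h, dims = dims,
                 coords = coords, extent = extent,
                 tumor_diameter = tumor_diameter,
                 tumor_center = c(0, 0, 0),
                 conductivities = c(tumor = conductivities[1],
                                    background = conductivities[2]),
                 electrodes = electrodes),
            class = "tissue_domain")
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf("Tissue domain: %d x %d x %d voxels at %g mm (%g x %g x %g mm)\n",
              x$dims[1], x$dims[2], x$dims[3], x$h,
              x$extent[1], x$extent[2], x$extent[3]))
  cat(sprintf("  tumor diameter: %g mm (%d voxels), sigma tumor/background: %g / %g S/m\n",
              x$tumor_diameter, sum(x$labels == .LAB_TUMOR),
              x$conductivities[["tumor"]], x$conductivities[["background"]]))
  invisible(x)
}

#' Tumor voxel mask of a domain
#'
#' @param domain a `tissue_domain`.
#' @return Logical array marking tumor voxels.
#' @export
tumor_mask <- function(domain) domain$labels == .LAB_TUMOR
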