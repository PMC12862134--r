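#' Solve the quasi-static electric field
#'
#' Solves the potential problem `div(sigma grad phi) = 0` on the voxel grid
#' of a [build_domain()] result, with Dirichlet potentials +V/2 and -V/2 on
#' the two electrode voxel sets and an insulating (zero normal current)
#' outer boundary, then returns the field magnitude `|grad phi|` in V/cm.
#' Discretization is a 7-point finite-difference stencil with harmonic
#' averaging of conductivity at cell faces, which keeps the normal current
#' continuous across the tumor/background conductivity jump. The symmetric
#' positive-definite system is solved by preconditioned conjugate gradients.
#'
#' @param domain a `tissue_domain` from [build_domain()].
#' @param electrodes an [electrode_config()]; defaults to the one the domain
#'   was built with. Only the applied voltage is taken from here, so the same
#'   domain can be re-driven at different voltages.
#' @param tolerance relative residual tolerance for the linear solve.
#' @param max_iter iteration cap for the conjugate-gradient solver.
#' @return An object of class `field_map` with elements `magnitude` (3-D
#'   array, V/cm), `phi` (V), `voltage`, `solver_residual`, `iterations`,
#'   plus the grid geometry.
#' @export
#' @examples
#' el <- electrode_config(spacing = 4, applied_voltage = 800)
#' dom <- build_domain(5, c(0.2, 0.1), el, resolution = 0.5)
#' fm <- solve_field(dom)
#' max(fm$magnitude)
solve_field <- function(domain, electrodes = domain$electrodes,
                        tolerance = 1e-6, max_iter = 50000) {
  stopifnot(inherits(domain, "tissue_domain"), tolerance > 0, max_iter > 0)
  V <- electrodes$applied_voltage
  sol <- .fd_solve_potential(as.integer(domain$labels),
                             as.numeric(domain$sigma),
                             domain$dims, V, tolerance, as.integer(max_iter))
  if (sol$relative_residual > tolerance)
    stop(sprintf("field solver did not converge: relative residual %.3g after %d iterations",
                 sol$relative_residual, sol$iterations))
  phi <- array(sol$phi, dim = domain$dims)
  # gradient is V per mm on the grid; 1 V/mm = 10 V/cm
  mag <- array(.fd_gradient_magnitude(sol$phi, domain$dims, domain$h) * 10,
               dim = domain$dims)
  structure(list(magnitude = mag, phi = phi, h = domain$h,
                 dims = domain$dims, coords = domain$coords,
                 voltage = V, electrodes = electrodes,
                 solver_residual = sol$relative_residual,
                 iterations = sol$iterations),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("Field map: %d x %d x %d voxels at %g mm, applied %g V\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, x$voltage))
  cat(sprintf("  |E| range: %.1f to %.1f V/cm; solver residual %.2g (%d iterations)\n",
              min(x$magnitude), max(x$magnitude), x$solver_residual,
              x$iterations))
  invisible(x)
}

#' Plot the equatorial field-magnitude slice
#'
#' @param x a `field_map`.
#' @param isolevel optional field level (V/cm) at which to draw a contour.
#' @param ... passed to [graphics::image()].
#' @export
plot.field_map <- function(x, isolevel = NULL, ...) {
  k0 <- (x$dims[3] + 1) / 2
  sl <- x$magnitude[, , k0]
  image(x$coords$x, x$coords$y, sl, xlab = "x (mm)", ylab = "y (mm)",
        main = "|E| (V/cm), equatorial plane", useRaster = TRUE, ...)
  if (!is.null(isolevel))
    graphics::contour(x$coords$x, x$coords$y, sl, levels = isolevel,
                      add = TRUE, lwd = 2)
  invisible(x)
}

#' Field magnitude along the inter-electrode axis
#'
#' Extracts `|E|` along the x axis through the inter-electrode midpoint
#' (y = z = 0), the line along which hydrogel lesion extents are measured.
#'
#' @param field a `field_map`.
#' @return Data frame with columns `x` (mm from midpoint) and `magnitude`
#'   (V/cm).
#' @export
field_axis_profile <- function(field) {
  j0 <- (field$dims[2] + 1) / 2
  k0 <- (field$dims[3] + 1) / 2
  data.frame(x = field$coords$x, magnitude = field$magnitude[, j0, k0])
}

#' Net current at each electrode
#'
#' Sums the conduction current through the faces between each electrode's
#' voxels and the surrounding medium. In a converged solution the current
#' entering one electrode balances the current leaving the other (charge
#' conservation); the imbalance is a solver-quality diagnostic.
#'
#' @param field a `field_map`.
#' @param domain the `tissue_domain` the field was solved on.
#' @return Named vector `c(plus = , minus = )` of signed currents (consistent
#'   arbitrary units; only their balance is meaningful).
#' @export
electrode_currents <- function(field, domain) {
  c(plus = .fd_electrode_current(as.numeric(field$phi),
                                 as.integer(domain$labels),
                                 as.numeric(domain$sigma),
                                 domain$dims, domain$h, .LAB_PLUS),
    minus = .fd_electrode_current(as.numeric(field$phi),
                                  as.integer(domain$labels),
                                  as.numeric(domain$sigma),
                                  domain$dims, domain$h, .LAB_MINUS))
}

#' Ideal uniform field between parallel plates
#'
#' The field magnitude in a parallel-plate (cuvette / 4-well) exposure:
#' applied voltage divided by the plate gap. 800 V across a 4-mm gap gives
#' 2,000 V/cm; 400 V gives 1,000 V/cm.
#'
#' @param voltage applied voltage in V (>= 0).
#' @param gap_mm plate gap in mm (> 0).
#' @return Field magnitude in V/cm.
#' @export
#' @examples
#' uniform_field(800, 4)   # 2000 V/cm
#' uniform_field(0, 8.5)   # 0
uniform_field <- function(voltage, gap_mm) {
  if (any(gap_mm <= 0)) stop("plate gap must be positive")
  if (any(voltage < 0)) stop("voltage must be non-negative")
  voltage / (gap_mm / 10)
}

#' Transmembrane field magnitude
#'
#' The electric field sustained across the lipid bilayer for a given induced
#' transmembrane potential: potential divided by membrane thickness, in
#' MV/m. A 1-V transmembrane potential across a 5-nm membrane corresponds
#' to 200 MV/m, the order of magnitude at which membrane proteins can be
#' destabilized during pulse delivery.
#'
#' @param transmembrane_potential potential in V (>= 0).
#' @param thickness_nm membrane thickness in nm (> 0).
#' @return Field magnitude in MV/m.
#' @export
#' @examples
#' membrane_field(1, 5) # 200 MV/m
membrane_field <- function(transmembrane_potential, thickness_nm) {
  if (any(thickness_nm <= 0)) stop("membrane thickness must be positive")
  if (any(transmembrane_potential < 0)) stop("potential must be non-negative")
  # V / nm = 1e9 V/m = 1e3 MV/m
  transmembrane_potential / thickness_nm * 1e3
}

#' Analytic midpoint field of a two-wire line
#'
#' Closed-form approximation for the field magnitude at the midpoint between
#' two long parallel cylindrical electrodes (radius `a`, center spacing `d`)
#' held at a potential difference `V` in a homogeneous medium:
#' `E = 2 V / (d ln((d - a) / a))`. Used as an independent oracle for the
#' finite-difference solver.
#'
#' @param voltage potential difference in V.
#' @param spacing_mm center-to-center spacing in mm.
#' @param radius_mm electrode radius in mm.
#' @return Midpoint field magnitude in V/cm.
#' @export
two_wire_midpoint_field <- function(voltage, spacing_mm, radius_mm) {
  stopifnot(spacing_mm > 2 * radius_mm)
  e_v_per_mm <- 2 * voltage / (spacing_mm * log((spacing_mm - radius_mm) / radius_mm))
  e_v_per_mm * 10
}
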