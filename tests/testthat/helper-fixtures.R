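# shared fixtures, built once per session

.fixture_env <- new.env(parent = emptyenv())

# hydrogel calibration field at a given resolution, cached
cached_hydrogel_field <- function(resolution = 0.2) {
  key <- sprintf("hydrogel_%g", resolution)
  if (is.null(.fixture_env[[key]])) {
    cfg <- hydrogel_config(resolution = resolution)
    .fixture_env[[key]] <- solve_hydrogel_field(cfg)
  }
  .fixture_env[[key]]
}

# hand-construct a tissue_domain / field_map pair on an arbitrary label and
# magnitude grid, for tests that need exact voxel control
make_synthetic_domain <- function(labels, h = 1) {
  dims <- dim(labels)
  coords <- lapply(dims, function(ni) (seq_len(ni) - (ni + 1) / 2) * h)
  names(coords) <- c("x", "y", "z")
  structure(list(labels = labels, sigma = array(1, dims), h = h,
                 dims = dims, coords = coords, extent = dims * h,
                 tumor_diameter = NA_real_, tumor_center = c(0, 0, 0),
                 conductivities = c(tumor = 1, background = 1),
                 electrodes = NULL),
            class = "tissue_domain")
}

make_synthetic_field <- function(magnitude, h = 1) {
  dims <- dim(magnitude)
  coords <- lapply(dims, function(ni) (seq_len(ni) - (ni + 1) / 2) * h)
  names(coords) <- c("x", "y", "z")
  structure(list(magnitude = magnitude, phi = array(0, dims), h = h,
                 dims = dims, coords = coords, voltage = NA_real_,
                 electrodes = NULL, solver_residual = 0, iterations = 0),
            class = "field_map")
}

# small, fast needle-pair solve used across field tests
cached_small_solve <- function() {
  if (is.null(.fixture_env$small)) {
    el <- electrode_config(spacing = 3, applied_voltage = 300,
                           electrode_radius = 0.5)
    dom <- build_domain(3.5, c(0.3, 0.1), el, resolution = 0.3)
    .fixture_env$small <- list(el = el, dom = dom, fm = solve_field(dom))
  }
  .fixture_env$small
}
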