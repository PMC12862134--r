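#' Read lesion measurements from CSV
#'
#' Expects columns `replicate_id` and either `extent_mm` or `area_mm2`
#' (optionally both columns present with exactly one filled per row).
#'
#' @param path CSV file path.
#' @return A [lesion_measurements()] table.
#' @export
read_lesion_csv <- function(path) {
  df <- read.csv(path)
  if (!"extent_mm" %in% names(df)) df$extent_mm <- NA_real_
  if (!"area_mm2" %in% names(df)) df$area_mm2 <- NA_real_
  lesion_measurements(df$replicate_id, df$extent_mm, df$area_mm2)
}

#' Read a field configuration from YAML
#'
#' Keys: `electrode` (`mode`, `spacing_mm`, `radius_mm`, `voltage_V`,
#'   optionally `exposed_length_mm`), `tissue` (`tumor_diameter_mm`,
#'   `sigma_tumor_S_per_m`, `sigma_background_S_per_m`), `grid`
#'   (`voxel_mm`, optionally `extent_mm`), `solver` (`tol`, `max_iter`).
#'
#' @param path YAML file path.
#' @return List with `electrodes` ([electrode_config()]), `tissue`, `grid`
#'   and `solver` entries ready for [build_domain()] / [solve_field()].
#' @export
read_field_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  el <- cfg$electrode
  electrodes <- electrode_config(
    mode = if (is.null(el$mode)) "needle_pair" else el$mode,
    spacing = el$spacing_mm,
    applied_voltage = el$voltage_V,
    electrode_radius = if (is.null(el$radius_mm)) 0.5 else el$radius_mm,
    exposed_length = el$exposed_length_mm)
  list(electrodes = electrodes,
       tissue = cfg$tissue,
       grid = cfg$grid,
       solver = if (is.null(cfg$solver)) list(tol = 1e-6, max_iter = 50000)
                else cfg$solver)
}

#' Solve a field from a configuration list
#'
#' @param config as returned by [read_field_config()].
#' @return List with `domain` and `field`.
#' @export
solve_from_config <- function(config) {
  ti <- config$tissue
  dom <- build_domain(ti$tumor_diameter_mm,
                      c(ti$sigma_tumor_S_per_m, ti$sigma_background_S_per_m),
                      config$electrodes,
                      resolution = config$grid$voxel_mm,
                      extent = config$grid$extent_mm)
  list(domain = dom,
       field = solve_field(dom, tolerance = config$solver$tol,
                           max_iter = config$solver$max_iter))
}

#' Export a field map as a legacy VTK structured-points file
#'
#' Writes the field-magnitude grid in ASCII legacy VTK format for
#' visualization in ParaView or similar tools.
#'
#' @param field a `field_map`.
#' @param path output file (conventionally `.vtk`).
#' @export
write_fieldmap_vtk <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "electric field magnitude (V/cm)",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", field$dims[1], field$dims[2],
                       field$dims[3]),
               sprintf("ORIGIN %g %g %g", field$coords$x[1],
                       field$coords$y[1], field$coords$z[1]),
               sprintf("SPACING %g %g %g", field$h, field$h, field$h),
               sprintf("POINT_DATA %d", prod(field$dims)),
               "SCALARS field_magnitude double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(field$magnitude), trim = TRUE, digits = 8), con)
  invisible(path)
}

#' Summarize the field within the tumor
#'
#' @param field a `field_map`.
#' @param domain the matching `tissue_domain`.
#' @param probs quantile probabilities.
#' @return One-row data frame: min, quantiles, max of `|E|` (V/cm) over
#'   tumor voxels.
#' @export
field_summary <- function(field, domain, probs = c(0.05, 0.5, 0.95)) {
  e <- field$magnitude[tumor_mask(domain)]
  q <- quantile(e, probs)
  out <- data.frame(min = min(e), t(q), max = max(e))
  names(out) <- c("min", sprintf("q%02d", round(100 * probs)), "max")
  out
}

#' Write a fluorescence frame series as multi-page TIFFs
#'
#' One two-page 16-bit TIFF per timepoint (page 1 green, page 2 deep-red),
#' named `<well>_t<hours>h.tif`, plus an `index.csv` with the acquisition
#' metadata.
#'
#' @param frames list of [fluor_frame()] objects.
#' @param dir output directory (created if missing).
#' @param max_intensity intensity mapped to the 16-bit maximum.
#' @return The index data frame, invisibly.
#' @export
write_fluor_frames <- function(frames, dir, max_intensity = 4096) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- do.call(rbind, lapply(frames, function(f) {
    file <- sprintf("%s_t%03dh.tif", f$well_id, round(f$timepoint_h))
    tiff::writeTIFF(list(pmin(f$green / max_intensity, 1),
                         pmin(f$deepred / max_intensity, 1)),
                    file.path(dir, file), bits.per.sample = 16)
    data.frame(file = file, well_id = f$well_id,
               timepoint_h = f$timepoint_h,
               pixel_size_um = f$pixel_size_um,
               max_intensity = max_intensity)
  }))
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read a fluorescence frame series written by [write_fluor_frames()]
#'
#' @param dir directory containing the TIFFs and `index.csv`.
#' @return List of [fluor_frame()] objects ordered by timepoint.
#' @export
read_fluor_frames <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"))
  idx <- idx[order(idx$timepoint_h), ]
  lapply(seq_len(nrow(idx)), function(i) {
    pages <- tiff::readTIFF(file.path(dir, idx$file[i]), all = TRUE)
    fluor_frame(idx$well_id[i], idx$timepoint_h[i],
                pages[[1]] * idx$max_intensity[i],
                pages[[2]] * idx$max_intensity[i],
                pixel_size_um = idx$pixel_size_um[i])
  })
}
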