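#' Field dose-response model for cell viability
#'
#' Phenomenological logistic model of viability after a uniform-field IRE
#' exposure, anchored to suspension-treatment viability brackets:
#' about 95% viable untreated, about 34% at 1,000 V/cm, and about 3% at
#' 2,000 V/cm. The form is
#' `viability(E) = baseline * (1 + exp(-m/w)) / (1 + exp((E - m)/w))`,
#' which equals `baseline` exactly at `E = 0` and decreases strictly with
#' field. The default midpoint (800 V/cm) and width (360 V/cm) place the
#' predictions at 0/1,000/2,000 V/cm inside those brackets; a plain
#' logistic centered on the lethal-lesion threshold (~525 V/cm) cannot hit
#' the 1,000 and 2,000 V/cm anchors simultaneously, so the suspension
#' midpoint sits higher than the lesion-boundary threshold.
#'
#' @param midpoint logistic midpoint in V/cm.
#' @param width logistic width in V/cm (> 0); the slope at the midpoint is
#'   proportional to 1/width.
#' @param baseline untreated viability fraction in (0, 1].
#' @return An object of class `dose_response_model`.
#' @export
#' @examples
#' m <- dose_response_model()
#' viability_at(c(0, 1000, 2000), m)
dose_response_model <- function(midpoint = 800, width = 360,
                                baseline = 0.9499) {
  stopifnot(midpoint > 0, width > 0, baseline > 0, baseline <= 1)
  structure(list(midpoint = midpoint, width = width, baseline = baseline),
            class = "dose_response_model")
}

#' Viability at a given field magnitude
#'
#' @param field field magnitude(s) in V/cm (>= 0).
#' @param model a [dose_response_model()].
#' @return Viability fraction(s).
#' @export
viability_at <- function(field, model = dose_response_model()) {
  stopifnot(all(field >= 0), inherits(model, "dose_response_model"))
  model$baseline * (1 + exp(-model$midpoint / model$width)) /
    (1 + exp((field - model$midpoint) / model$width))
}

#' Default hydrogel calibration configuration
#'
#' Two-needle electrodes in a uniform collagen hydrogel phantom: 4-mm
#' spacing, 0.5-mm needle radius, needles penetrating the full gel depth,
#' and a drive voltage placing the lethal isocontour well outside the
#' needle pair. The gel is modeled as a single homogeneous conductivity.
#'
#' @param applied_voltage drive voltage in V.
#' @param spacing needle spacing in mm.
#' @param conductivity gel conductivity in S/m.
#' @param resolution grid resolution in mm.
#' @return List with `electrodes`, `conductivity`, `resolution`.
#' @export
hydrogel_config <- function(applied_voltage = 1400, spacing = 4,
                            conductivity = 1.0, resolution = 0.1) {
  list(electrodes = electrode_config(spacing = spacing,
                                     applied_voltage = applied_voltage,
                                     electrode_radius = 0.5,
                                     exposed_length = Inf),
       conductivity = conductivity,
       resolution = resolution)
}

#' Solve the hydrogel calibration field
#'
#' @param config a [hydrogel_config()].
#' @return A `field_map` for the phantom (thin-slab grid; the penetrating
#'   needles make the solution depth-invariant).
#' @export
solve_hydrogel_field <- function(config = hydrogel_config()) {
  sp <- config$electrodes$spacing
  dom <- build_domain(0, config$conductivity, config$electrodes,
                      resolution = config$resolution,
                      extent = c(4 * sp, 4 * sp, 5 * config$resolution))
  solve_field(dom)
}

# decaying branch of the axis profile: x beyond the outer electrode edge
.decaying_branch <- function(field) {
  el <- field$electrodes
  prof <- field_axis_profile(field)
  keep <- prof$x > el$spacing / 2 + el$electrode_radius + field$h
  prof[keep, ]
}

#' Generate synthetic hydrogel lesion measurements
#'
#' Emulates the hydrogel calibration experiment: the configured field is
#' solved, the axis extent of the ground-truth lethal isocontour is located
#' on the decaying branch of the field profile (beyond the needles), and
#' each replicate's extent is perturbed multiplicatively,
#' `extent * (1 + eps)` with `eps ~ Normal(0, noise_cv)`.
#'
#' @param truth_threshold ground-truth lethal threshold in V/cm.
#' @param config a [hydrogel_config()].
#' @param noise_cv coefficient of variation of the extent measurement.
#' @param n number of replicates.
#' @param seed RNG seed.
#' @param field optionally a pre-solved `field_map` for the same config (to
#'   avoid re-solving across repeated experiments).
#' @return A [lesion_measurements()] table with attributes `field` (the
#'   solved map), `truth_extent` (noiseless extent, mm) and
#'   `truth_threshold`.
#' @export
gen_hydrogel_lesions <- function(truth_threshold = 500,
                                 config = hydrogel_config(),
                                 noise_cv = 0.05, n = 5, seed = NULL,
                                 field = NULL) {
  stopifnot(truth_threshold > 0, noise_cv >= 0, n >= 1)
  if (is.null(field)) field <- solve_hydrogel_field(config)
  br <- .decaying_branch(field)
  if (truth_threshold > max(br$magnitude) || truth_threshold < min(br$magnitude))
    stop("truth isocontour outside the attainable range of this field map")
  x_cross <- approx(br$magnitude, br$x, xout = truth_threshold)$y
  truth_extent <- 2 * x_cross
  extents <- local_seed(seed, truth_extent * (1 + rnorm(n, 0, noise_cv)))
  out <- lesion_measurements(seq_len(n), extent_mm = extents)
  attr(out, "field") <- field
  attr(out, "truth_extent") <- truth_extent
  attr(out, "truth_threshold") <- truth_threshold
  out
}

# relative viable fraction over time for one treatment arm; field in V/cm
.viable_fraction <- function(t_h, field, cart, model) {
  v0 <- model$baseline
  if (field <= 0 && !cart)           # control: slow growth
    return(1 + 0.002 * t_h)
  if (field <= 0 && cart)            # CAR-T only: outer-layer kill, late drop
    return(1 - 0.4 * pmax(0, t_h - 48) / 24)
  relmin <- viability_at(field, model) / v0
  if (t_h < 3) return(1)
  if (cart)                          # combination: no rebound, slow decay
    return(relmin * exp(-(t_h - 3) / 60))
  if (field <= 1500) {               # incomplete treatment: rebound
    relcap <- relmin + 0.6 * (1 - relmin)
    return(relmin + (relcap - relmin) * (1 - exp(-(t_h - 3) / 30)))
  }
  relmin                             # complete treatment: flat
}

# spheroid radius factor: swelling with field after treatment, outside-in
# erosion under CAR-T
.radius_factor <- function(t_h, field, cart) {
  f <- 1
  if (field > 0 && t_h >= 3)
    f <- f * (1 + 0.05 + 0.10 * max(0, field - 1000) / 1500)
  if (cart)
    f <- f * (1 - 0.25 * max(0, t_h - 3) / 69)
  f
}

#' Generate a synthetic spheroid fluorescence time-lapse
#'
#' Emulates the two-channel spheroid assay: a disk-shaped spheroid whose
#' green intensity scales with the viable cell fraction given by the
#' dose-response model, with post-treatment swelling increasing with field,
#' logistic-style regrowth when the field is at or below 1,500 V/cm without
#' CAR T cells, outside-in radius erosion under CAR-T treatment, and a
#' deep-red CAR T-cell channel that surrounds the spheroid and infiltrates
#' it (early only when combined with IRE). Pixel noise is Poisson shot
#' noise plus Gaussian read noise.
#'
#' @param field uniform treatment field in V/cm (0 = no IRE).
#' @param cart logical; CAR T cells added after treatment.
#' @param model a [dose_response_model()].
#' @param well_id identifier for the generated well.
#' @param timepoints_h acquisition times in hours; must include 0 and reach
#'   at least 72.
#' @param size_px image edge length in pixels.
#' @param radius_px spheroid radius at baseline in pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @param green_peak,deepred_peak,background mean intensities.
#' @param read_noise_sd Gaussian read-noise SD.
#' @param seed RNG seed.
#' @return List of [fluor_frame()] objects, one per timepoint, with the
#'   programmed ground truth attached as attribute `truth` (per-timepoint
#'   viable fraction and radius).
#' @export
gen_spheroid_timelapse <- function(field = 0, cart = FALSE,
                                   model = dose_response_model(),
                                   well_id = "well",
                                   timepoints_h = c(0, 3, 24, 48, 72),
                                   size_px = 192, radius_px = 55,
                                   pixel_size_um = 10,
                                   green_peak = 200, deepred_peak = 120,
                                   background = 20, read_noise_sd = 2,
                                   seed = NULL) {
  stopifnot(0 %in% timepoints_h, max(timepoints_h) >= 72,
            !is.unsorted(timepoints_h, strictly = TRUE))
  ctr <- (size_px + 1) / 2
  d2 <- outer((seq_len(size_px) - ctr)^2, (seq_len(size_px) - ctr)^2, `+`)
  local_seed(seed, {
    frames <- vector("list", length(timepoints_h))
    truth <- data.frame(timepoint_h = timepoints_h, viable_fraction = NA_real_,
                        radius_px = NA_real_)
    for (i in seq_along(timepoints_h)) {
      t_h <- timepoints_h[i]
      rel <- .viable_fraction(t_h, field, cart, model)
      r <- radius_px * .radius_factor(t_h, field, cart)
      disk <- d2 <= r^2
      g_mean <- background + green_peak * rel * disk
      dr_mean <- matrix(background / 2, size_px, size_px)
      if (cart && t_h >= 3) {
        ring <- d2 > r^2 & d2 <= (r + 8)^2
        dr_mean[ring] <- dr_mean[ring] + deepred_peak
        infil <- if (field > 0) 0.5
                 else 0.1 + 0.5 * max(0, t_h - 3) / 69
        dr_mean[disk] <- dr_mean[disk] + deepred_peak * infil
      }
      npix <- size_px^2
      green <- matrix(rpois(npix, as.numeric(g_mean)) +
                        rnorm(npix, 0, read_noise_sd), size_px, size_px)
      deepred <- matrix(rpois(npix, as.numeric(dr_mean)) +
                          rnorm(npix, 0, read_noise_sd), size_px, size_px)
      green[green < 0] <- 0
      deepred[deepred < 0] <- 0
      frames[[i]] <- fluor_frame(well_id, t_h, green, deepred, pixel_size_um)
      truth$viable_fraction[i] <- rel
      truth$radius_px[i] <- r
    }
    attr(frames, "truth") <- truth
    frames
  })
}

#' Quantify a generated (or measured) frame series into a track
#'
#' Convenience wrapper: segments every frame, computes per-frame metrics,
#' and normalizes to the first timepoint.
#'
#' @param frames list of [fluor_frame()] objects.
#' @return A `spheroid_track`.
#' @export
track_frames <- function(frames) {
  metrics <- do.call(rbind, lapply(frames, function(f) frame_metrics(f)))
  normalize_track(metrics)
}

#' Cohort specification for the synthetic in-vivo study
#'
#' Defaults mirror the survival-study design: four groups (sham, CAR-T,
#' IRE, combination) of 6 animals, thrice-weekly caliper measurement,
#' treatment once the tumor exceeds 100 mm^3, eradication within 48 h of
#' IRE, recurrence of 4/6 expected in the IRE-only arm, none in the
#' combination arm, euthanasia at 12 mm in any direction, and censoring at
#' day 60. Growth is exponential with per-animal lognormal rate
#' heterogeneity.
#'
#' @param n_per_group animals per group.
#' @param initial_volume_mm3 inoculation-day tumor volume.
#' @param growth_rate_per_day median exponential growth rate.
#' @param rate_sdlog lognormal SD of the per-animal rate.
#' @param cart_growth_factor growth-rate multiplier for CAR-T-only animals.
#' @param recurrence_probability per-animal recurrence probability in the
#'   IRE-only arm.
#' @param recurrence_delay_range days post-treatment within which a
#'   recurrence emerges (uniform).
#' @param regrowth_volume_mm3 volume at the recurrence measurement.
#' @param measurement_noise_cv multiplicative caliper noise.
#' @param followup_end last follow-up day.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 6, initial_volume_mm3 = 2,
                        growth_rate_per_day = 0.14, rate_sdlog = 0.15,
                        cart_growth_factor = 0.85,
                        recurrence_probability = 4 / 6,
                        recurrence_delay_range = c(10, 25),
                        regrowth_volume_mm3 = 1,
                        measurement_noise_cv = 0.05,
                        followup_end = 60) {
  stopifnot(n_per_group >= 1, recurrence_probability >= 0,
            recurrence_probability <= 1, initial_volume_mm3 > 0,
            growth_rate_per_day > 0, followup_end > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# thrice-weekly measurement schedule (e.g. Mon/Wed/Fri)
.measurement_days <- function(followup_end) {
  d <- 0:followup_end
  d[d %% 7 %in% c(0, 2, 4)]
}

#' Generate a synthetic in-vivo cohort
#'
#' Simulates caliper series and outcomes for the four study arms. Sham and
#' CAR-T-only tumors grow continuously (CAR-T slightly slower); IRE and
#' combination tumors are eradicated at the first measurement at or after
#' 48 h post-treatment; IRE-only tumors recur with the configured
#' probability after a random delay; combination tumors never recur.
#' Animals are euthanized when any caliper dimension reaches 12 mm and
#' censored at the end of follow-up. Calipers are derived from volume
#' assuming a 1.2:1 axis ratio.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed.
#' @return List with `calipers` (animal_id, group, day, length_mm,
#'   width_mm), and `subjects` (animal_id, group, treatment_day,
#'   endpoint_day, event, programmed_label, recurrence_day).
#' @export
gen_invivo_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("sham", "CAR-T", "IRE", "combination")
  days <- .measurement_days(spec$followup_end)
  local_seed(seed, {
    cal_rows <- list(); subj_rows <- list(); id <- 0
    for (g in groups) {
      for (a in seq_len(spec$n_per_group)) {
        id <- id + 1
        animal <- sprintf("%s_%02d", g, a)
        rate <- spec$growth_rate_per_day * rlnorm(1, 0, spec$rate_sdlog)
        if (g == "CAR-T") rate <- rate * spec$cart_growth_factor
        vol_true <- spec$initial_volume_mm3 * exp(rate * days)
        noise <- 1 + rnorm(length(days), 0, spec$measurement_noise_cv)
        vol_obs <- pmax(0, vol_true * noise)
        tr_idx <- which(treatment_trigger(vol_obs))[1]
        if (is.na(tr_idx))
          stop(sprintf("animal %s never reached the treatment trigger", animal))
        treatment_day <- days[tr_idx]
        recurrence_day <- NA_real_
        label <- "stable_or_progressive"
        if (g %in% c("IRE", "combination")) {
          post <- days >= treatment_day + 2
          vol_obs[post] <- 0
          label <- "eradicated_durable"
          recurs <- g == "IRE" && runif(1) < spec$recurrence_probability
          if (recurs) {
            delay <- runif(1, spec$recurrence_delay_range[1],
                           spec$recurrence_delay_range[2])
            rec_candidates <- days[days >= treatment_day + 2 + delay]
            if (length(rec_candidates) > 0) {
              recurrence_day <- rec_candidates[1]
              regrow <- days >= recurrence_day
              vol_obs[regrow] <- spec$regrowth_volume_mm3 *
                exp(rate * (days[regrow] - recurrence_day)) *
                (1 + rnorm(sum(regrow), 0, spec$measurement_noise_cv))
              vol_obs[regrow] <- pmax(vol_obs[regrow],
                                      spec$regrowth_volume_mm3 / 2)
              label <- "eradicated_recurrent"
            }
          }
        }
        width <- (vol_obs / 0.6)^(1 / 3)
        length_ <- 1.2 * width
        endpoint_idx <- which(endpoint_trigger(length_, width))[1]
        if (!is.na(endpoint_idx)) {
          keep <- seq_len(endpoint_idx)
          endpoint_day <- days[endpoint_idx]
          event <- "death/euthanasia"
        } else {
          keep <- seq_along(days)
          endpoint_day <- spec$followup_end
          event <- "censored"
        }
        cal_rows[[id]] <- data.frame(animal_id = animal, group = g,
                                     day = days[keep],
                                     length_mm = length_[keep],
                                     width_mm = width[keep])
        subj_rows[[id]] <- data.frame(animal_id = animal, group = g,
                                      treatment_day = treatment_day,
                                      endpoint_day = endpoint_day,
                                      event = event,
                                      programmed_label = label,
                                      recurrence_day = recurrence_day)
      }
    }
    list(calipers = do.call(rbind, cal_rows),
         subjects = do.call(rbind, subj_rows))
  })
}
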