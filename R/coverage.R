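#' Electrode spacing rule for needle placement
#'
#' The treatment convention: needle spacing is set 1 mm below the maximum
#' tumor diameter so both needles insert into the tumor. A 6-mm tumor gets a
#' 5-mm spacing.
#'
#' @param max_tumor_diameter maximum tumor diameter in mm (> 1).
#' @return Spacing in mm.
#' @export
#' @examples
#' spacing_rule(6) # 5
spacing_rule <- function(max_tumor_diameter) {
  if (any(max_tumor_diameter <= 1))
    stop("tumor diameter must exceed 1 mm for the spacing rule")
  max_tumor_diameter - 1
}

#' Default Monte-Carlo sampling ranges for planning scenarios
#'
#' Tumor diameters span the subcutaneous range 4 to 8 mm. Conductivity
#' ranges are literature-typical for soft tumor tissue (0.1 to 0.5 S/m) and
#' subcutaneous fat-dominated background (0.02 to 0.2 S/m); they are not
#' measured values and should be adapted when tissue data are available.
#'
#' @return Named list of `c(low, high)` ranges.
#' @export
planning_ranges <- function() {
  list(tumor_diameter = c(4, 8),
       tumor_conductivity = c(0.1, 0.5),
       background_conductivity = c(0.02, 0.2))
}

# truncated-normal sampler by rejection; ranges here are a few SD wide so
# acceptance is high
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Sample randomized planning scenarios
#'
#' Draws Monte-Carlo scenarios for dose planning: tumor diameter uniform
#' over its range, tumor and background conductivities uniform over theirs,
#' and the lethal threshold from a normal distribution truncated to the
#' calibrated range. Electrode spacing follows [spacing_rule()].
#'
#' @param n number of scenarios.
#' @param threshold a `threshold_estimate` (calibrated distribution).
#' @param ranges sampling ranges as from [planning_ranges()].
#' @param seed master seed; scenario draws and the per-scenario seeds are
#'   reproducible given the same seed.
#' @param threshold_fixed if `TRUE`, every scenario uses the mean threshold
#'   (mean-only planning); if `"worst_case"`, every scenario uses the
#'   calibrated maximum.
#' @return Data frame of class `planning_scenarios`.
#' @export
#' @examples
#' th <- threshold_estimate(525, 77, 442, 613, n = 5)
#' sc <- sample_scenarios(5, th, seed = 1)
#' range(sc$tumor_diameter)
sample_scenarios <- function(n, threshold, ranges = planning_ranges(),
                             seed = NULL, threshold_fixed = FALSE) {
  stopifnot(n >= 1, inherits(threshold, "threshold_estimate"))
  for (r in ranges)
    if (r[1] > r[2]) stop("degenerate sampling range (low > high)")
  local_seed(seed, {
    d <- runif(n, ranges$tumor_diameter[1], ranges$tumor_diameter[2])
    st <- runif(n, ranges$tumor_conductivity[1], ranges$tumor_conductivity[2])
    sb <- runif(n, ranges$background_conductivity[1],
                ranges$background_conductivity[2])
    th <- if (identical(threshold_fixed, "worst_case")) {
      rep(threshold$maximum, n)
    } else if (isTRUE(threshold_fixed)) {
      rep(threshold$mean, n)
    } else {
      rnorm_trunc(n, threshold$mean, threshold$sd,
                  threshold$minimum, threshold$maximum)
    }
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    out <- data.frame(scenario_id = seq_len(n), tumor_diameter = d,
                      tumor_conductivity = st, background_conductivity = sb,
                      threshold = th, spacing = spacing_rule(d),
                      rng_seed = sub_seeds)
    class(out) <- c("planning_scenarios", "data.frame")
    out
  })
}

#' Fraction of tumor covered by the lethal field
#'
#' The planning endpoint: the fraction of tumor voxels whose field magnitude
#' is at or above the lethal threshold.
#'
#' @param field a `field_map`.
#' @param domain the `tissue_domain` sharing the field's grid.
#' @param threshold lethal threshold in V/cm.
#' @return Coverage fraction in `[0, 1]`.
#' @export
compute_coverage <- function(field, domain, threshold) {
  stopifnot(identical(field$dims, domain$dims))
  tm <- tumor_mask(domain)
  if (!any(tm)) stop("domain has no tumor voxels")
  mean(field$magnitude[tm] >= threshold)
}

#' Run the Monte-Carlo coverage plan
#'
#' For each scenario, builds the two-needle domain, solves the field once at
#' unit applied voltage, and evaluates tumor coverage at every candidate
#' voltage-to-distance ratio by exact linear scaling of the field (the
#' potential problem is linear in the applied voltage, so one solve per
#' scenario suffices). Returns the full scenario-by-ratio coverage table and
#' a per-ratio mean/SD summary.
#'
#' @param scenarios a `planning_scenarios` table.
#' @param candidate_ratios ascending candidate voltage-to-distance ratios in
#'   V/cm; default 1,000 to 3,000 in 500-V/cm steps.
#' @param resolution planning grid resolution in mm.
#' @param tolerance,max_iter solver settings.
#' @param progress print a line per scenario.
#' @return An object of class `coverage_result` with elements `table`
#'   (scenario_id, ratio, coverage), `summary` (ratio, mean, sd, n),
#'   `scenarios`, and `failed` (scenario ids whose solve failed).
#' @export
run_plan <- function(scenarios, candidate_ratios = seq(1000, 3000, by = 500),
                     resolution = 0.25, tolerance = 1e-6, max_iter = 50000,
                     progress = FALSE) {
  stopifnot(nrow(scenarios) >= 1, all(candidate_ratios > 0),
            !is.unsorted(candidate_ratios, strictly = TRUE))
  rows <- vector("list", nrow(scenarios))
  failed <- integer(0)
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    res <- tryCatch({
      el <- electrode_config(spacing = sc$spacing, applied_voltage = 1)
      dom <- build_domain(sc$tumor_diameter,
                          c(sc$tumor_conductivity, sc$background_conductivity),
                          el, resolution = resolution)
      fm <- solve_field(dom, tolerance = tolerance, max_iter = max_iter)
      e_per_volt <- fm$magnitude[tumor_mask(dom)]   # V/cm per applied volt
      # ratio r V/cm across spacing s mm -> applied voltage r * s / 10 V
      volts <- candidate_ratios * sc$spacing / 10
      cov <- vapply(volts, function(v) mean(e_per_volt * v >= sc$threshold),
                    numeric(1))
      data.frame(scenario_id = sc$scenario_id, ratio = candidate_ratios,
                 coverage = cov)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("scenario %d failed: %s", sc$scenario_id,
                      conditionMessage(res)))
      failed <- c(failed, sc$scenario_id)
    } else {
      rows[[i]] <- res
      if (progress)
        message(sprintf("scenario %d/%d (d = %.1f mm) done",
                        i, nrow(scenarios), sc$tumor_diameter))
    }
  }
  if (length(failed) > 0.1 * nrow(scenarios))
    stop("more than 10% of planning scenarios failed to solve")
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summ <- do.call(rbind, lapply(split(tab, tab$ratio), function(d)
    data.frame(ratio = d$ratio[1], mean = mean(d$coverage),
               sd = sd(d$coverage), n = nrow(d))))
  summ <- summ[order(summ$ratio), ]
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, scenarios = scenarios,
                 failed = failed),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("Coverage plan: %d scenarios x %d candidate ratios\n",
              length(unique(x$table$scenario_id)), nrow(x$summary)))
  print(transform(x$summary, mean = round(mean, 4), sd = round(sd, 4)))
  invisible(x)
}

#' @export
plot.coverage_result <- function(x, ...) {
  s <- x$summary
  plot(s$ratio, 100 * s$mean, type = "b", pch = 19, ylim = c(0, 100),
       xlab = "voltage-to-distance ratio (V/cm)",
       ylab = "tumor coverage (%)", ...)
  graphics::arrows(s$ratio, 100 * pmax(0, s$mean - s$sd),
                   s$ratio, 100 * pmin(1, s$mean + s$sd),
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Select the minimal fully ablating dose
#'
#' Scans the coverage table for the smallest candidate ratio at which every
#' scenario reaches complete coverage (all tumor voxels at or above the
#' lethal threshold). If no candidate fully ablates every scenario, the
#' largest candidate is returned flagged as incomplete.
#'
#' @param result a `coverage_result` from [run_plan()].
#' @return An object of class `dose_plan`: `selected_ratio` (V/cm),
#'   `complete` flag, `candidate_ratios`, `applied_voltages` (per scenario,
#'   V), and the decision rule.
#' @export
select_dose <- function(result) {
  stopifnot(inherits(result, "coverage_result"), nrow(result$table) > 0)
  ratios <- sort(unique(result$table$ratio))
  full <- vapply(ratios, function(r) {
    all(result$table$coverage[result$table$ratio == r] >= 1)
  }, logical(1))
  complete <- any(full)
  selected <- if (complete) ratios[which(full)[1]] else ratios[length(ratios)]
  structure(list(selected_ratio = selected, complete = complete,
                 candidate_ratios = ratios,
                 applied_voltages = selected * result$scenarios$spacing / 10,
                 decision_rule = "smallest candidate ratio with coverage 1.0 in every scenario"),
            class = "dose_plan")
}

#' Sensitivity of the selected dose to planning assumptions
#'
#' The conductivity sampling ranges and the candidate-ratio step are
#' modeling choices, so the selected dose should be read together with its
#' sensitivity to them. This helper re-runs the full plan under a set of
#' perturbed configurations and tabulates the selected ratio for each.
#'
#' @param threshold a `threshold_estimate`.
#' @param n scenarios per configuration.
#' @param seed master seed (shared across configurations so only the
#'   perturbation differs).
#' @param resolution planning grid resolution in mm; the default is coarser
#'   than the headline plan because the table needs several full plans.
#' @return Data frame: `variation`, `selected_ratio`, `complete`.
#' @export
plan_sensitivity <- function(threshold, n = 30, seed = 1, resolution = 0.5) {
  base <- planning_ranges()
  narrow <- base
  narrow$tumor_conductivity <- c(0.2, 0.4)
  narrow$background_conductivity <- c(0.05, 0.15)
  muscle_like <- base
  muscle_like$background_conductivity <- c(0.2, 0.5)
  configs <- list(
    default = list(ranges = base, ratios = seq(1000, 3000, 500),
                   fixed = FALSE),
    threshold_mean_only = list(ranges = base, ratios = seq(1000, 3000, 500),
                               fixed = TRUE),
    threshold_worst_case = list(ranges = base, ratios = seq(1000, 3000, 500),
                                fixed = "worst_case"),
    narrow_conductivities = list(ranges = narrow,
                                 ratios = seq(1000, 3000, 500),
                                 fixed = FALSE),
    conductive_background = list(ranges = muscle_like,
                                 ratios = seq(1000, 3000, 500),
                                 fixed = FALSE),
    ratio_step_250 = list(ranges = base, ratios = seq(1000, 3000, 250),
                          fixed = FALSE))
  rows <- lapply(names(configs), function(nm) {
    cf <- configs[[nm]]
    sc <- sample_scenarios(n, threshold, ranges = cf$ranges, seed = seed,
                           threshold_fixed = cf$fixed)
    dp <- select_dose(run_plan(sc, candidate_ratios = cf$ratios,
                               resolution = resolution))
    data.frame(variation = nm, selected_ratio = dp$selected_ratio,
               complete = dp$complete)
  })
  do.call(rbind, rows)
}

#' @export
print.dose_plan <- function(x, ...) {
  cat(sprintf("Selected voltage-to-distance ratio: %g V/cm%s\n",
              x$selected_ratio,
              if (x$complete) "" else " (INCOMPLETE: no candidate fully ablated every scenario)"))
  cat(sprintf("  candidates: %s V/cm\n", paste(x$candidate_ratios, collapse = ", ")))
  cat(sprintf("  per-scenario applied voltage: %.0f to %.0f V\n",
              min(x$applied_voltages), max(x$applied_voltages)))
  invisible(x)
}
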