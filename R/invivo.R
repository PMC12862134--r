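#' Caliper tumor volume
#'
#' The standard ellipsoid approximation from two-axis caliper measurements:
#' `volume = 0.5 * length * width^2`, with length the larger axis. Inputs
#' given in the wrong order are swapped with a warning.
#'
#' @param length_mm,width_mm caliper measurements in mm (vectorized).
#' @return Volume in mm^3.
#' @export
#' @examples
#' tumor_volume(8, 5) # 100 mm^3, the treatment trigger volume
tumor_volume <- function(length_mm, width_mm) {
  stopifnot(all(length_mm >= 0), all(width_mm >= 0))
  swapped <- width_mm > length_mm
  if (any(swapped)) {
    warning("width exceeds length for some measurements; axes reordered")
    tmp <- length_mm[swapped]
    length_mm[swapped] <- width_mm[swapped]
    width_mm[swapped] <- tmp
  }
  0.5 * length_mm * width_mm^2
}

#' Treatment trigger
#'
#' Animals are treated once the tumor volume strictly exceeds 100 mm^3.
#'
#' @param volume_mm3 tumor volume in mm^3.
#' @return Logical.
#' @export
treatment_trigger <- function(volume_mm3) {
  stopifnot(all(volume_mm3 >= 0))
  volume_mm3 > 100
}

#' Humane endpoint trigger
#'
#' Euthanasia is triggered when the tumor reaches 12 mm in any direction.
#'
#' @param length_mm,width_mm caliper measurements in mm.
#' @return Logical.
#' @export
endpoint_trigger <- function(length_mm, width_mm) {
  stopifnot(all(length_mm >= 0), all(width_mm >= 0))
  pmax(length_mm, width_mm) >= 12
}

#' Classify a subject's post-treatment response
#'
#' Labels each subject from its volume series relative to treatment:
#' \describe{
#'   \item{eradicated_durable}{volume is zero at the first measurement at or
#'     beyond 48 h post-treatment and stays zero.}
#'   \item{eradicated_recurrent}{eradicated as above, but a later
#'     measurement is positive again; the progression day is the first
#'     recurrence day.}
#'   \item{stable_or_progressive}{never eradicated; the progression day is
#'     the first post-treatment day whose volume exceeds the pre-treatment
#'     volume (NA if never).}
#' }
#' Measurements are thrice-weekly, so "within 48 h" is operationalized as
#' the first scheduled measurement at or after treatment day + 2.
#'
#' @param days measurement days (from inoculation).
#' @param volumes tumor volumes (mm^3) at those days.
#' @param treatment_day day of treatment.
#' @return List with `label` and `progression_day` (NA if none).
#' @export
classify_response <- function(days, volumes, treatment_day) {
  stopifnot(length(days) == length(volumes), all(volumes >= 0))
  o <- order(days)
  days <- days[o]; volumes <- volumes[o]
  post <- which(days >= treatment_day + 2)
  if (length(post) == 0) stop("no post-treatment measurements")
  pre_idx <- which(days <= treatment_day)
  pre_volume <- if (length(pre_idx)) volumes[max(pre_idx)] else volumes[1]
  eradicated <- volumes[post[1]] == 0
  if (eradicated) {
    later <- post[-1]
    rec <- later[volumes[later] > 0]
    if (length(rec) == 0)
      list(label = "eradicated_durable", progression_day = NA_real_)
    else
      list(label = "eradicated_recurrent", progression_day = days[rec[1]])
  } else {
    prog <- post[volumes[post] > pre_volume]
    list(label = "stable_or_progressive",
         progression_day = if (length(prog)) days[prog[1]] else NA_real_)
  }
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. Censored subjects leave
#' the risk set without a survival drop. Computed via the survival package's
#' estimator and returned as a plain step-function table.
#'
#' @param time event or censoring times (>= 0).
#' @param event 1 (or TRUE) for an event, 0 for censoring.
#' @return Data frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `survival`, starting from (0, n, 0, 1).
#' @export
#' @examples
#' km_estimate(c(1, 2), c(1, 1))
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0), length(time) > 0)
  fit <- survival::survfit(survival::Surv(time, as.numeric(event)) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(length(time), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    survival = c(1, fit$surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
plot.km_curve <- function(x, add = FALSE, ...) {
  if (!add)
    plot(NA, xlim = range(x$time), ylim = c(0, 1), xlab = "time",
         ylab = "survival probability", ...)
  lines(stats::stepfun(x$time[-1], x$survival), do.points = FALSE, ...)
  invisible(x)
}

#' Pairwise log-rank tests with Bonferroni correction
#'
#' Runs the standard (unweighted) log-rank test for every pair of groups and
#' applies the Bonferroni correction `p_adjusted = min(1, p * k)`, with `k`
#' defaulting to the number of pairwise comparisons.
#'
#' @param time event/censoring times.
#' @param event event indicators (1 = event).
#' @param group group labels.
#' @param k_comparisons Bonferroni multiplier; defaults to `choose(G, 2)`.
#' @return Data frame: `group1`, `group2`, `statistic` (log-rank
#'   chi-square), `p`, `p_adjusted`.
#' @export
logrank_pairwise <- function(time, event, group, k_comparisons = NULL) {
  group <- as.factor(group)
  stopifnot(nlevels(group) >= 2,
            length(time) == length(event), length(time) == length(group))
  if (any(table(group) == 0)) stop("every group needs at least one subject")
  pairs <- combn(levels(group), 2)
  if (is.null(k_comparisons)) k_comparisons <- ncol(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    sel <- group %in% pairs[, j]
    if (sum(event[sel]) == 0) {
      # no events in either arm: the log-rank statistic is degenerate (0/0);
      # report no evidence of a difference
      stat <- 0
    } else {
      sd_ <- suppressWarnings(survival::survdiff(
        survival::Surv(time[sel], as.numeric(event[sel])) ~
          droplevels(group[sel])))
      stat <- sd_$chisq
      if (!is.finite(stat)) stat <- 0
    }
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               statistic = stat,
               p = pchisq(stat, df = 1, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p, k_comparisons)
  out
}

#' Bonferroni adjustment with capping
#'
#' @param p raw p-values.
#' @param k number of comparisons.
#' @return `min(1, p * k)` elementwise.
#' @export
bonferroni_adjust <- function(p, k) pmin(1, p * k)

#' Progression-free and overall survival tables for a cohort
#'
#' Derives per-subject survival inputs from caliper series:
#' \itemize{
#'   \item PFS: time from treatment to the first progression or recurrence
#'     event from [classify_response()]; subjects without an event are
#'     censored at the end of follow-up.
#'   \item OS: time from treatment to death/euthanasia; subjects alive at
#'     the end of follow-up are censored there.
#' }
#'
#' @param calipers data frame with `animal_id`, `group`, `day`,
#'   `length_mm`, `width_mm`.
#' @param subjects data frame with `animal_id`, `group`, `treatment_day`,
#'   `endpoint_day`, `event` (`"death/euthanasia"` or `"censored"`).
#' @param followup_end last follow-up day (from inoculation).
#' @return Data frame: `animal_id`, `group`, `response`, `pfs_time`,
#'   `pfs_event`, `os_time`, `os_event`.
#' @export
survival_tables <- function(calipers, subjects, followup_end = 60) {
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    cal <- calipers[calipers$animal_id == s$animal_id, ]
    vol <- tumor_volume(cal$length_mm, cal$width_mm)
    cls <- classify_response(cal$day, vol, s$treatment_day)
    pfs_event <- !is.na(cls$progression_day)
    pfs_time <- if (pfs_event) cls$progression_day - s$treatment_day
                else followup_end - s$treatment_day
    os_event <- s$event == "death/euthanasia"
    os_time <- (if (os_event) s$endpoint_day else followup_end) - s$treatment_day
    data.frame(animal_id = s$animal_id, group = s$group,
               response = cls$label,
               pfs_time = pfs_time, pfs_event = as.numeric(pfs_event),
               os_time = os_time, os_event = as.numeric(os_event))
  })
  do.call(rbind, rows)
}
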