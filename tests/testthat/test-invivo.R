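test_that("caliper volume follows the half length-width-squared formula", {
  expect_equal(tumor_volume(8, 5), 100)
  expect_equal(tumor_volume(6, 6), 108)
  expect_equal(tumor_volume(10, 0), 0)
  expect_warning(v <- tumor_volume(5, 8), "reordered")
  expect_equal(v, 100)
  # homogeneous of degree 3 under uniform scaling
  for (k in c(0.5, 2, 3)) {
    expect_equal(tumor_volume(k * 8, k * 5), k^3 * tumor_volume(8, 5))
  }
})

test_that("treatment trigger is strictly above 100 mm^3", {
  expect_false(treatment_trigger(100))
  expect_true(treatment_trigger(100.1))
  expect_false(treatment_trigger(0))
})

test_that("endpoint trigger fires at 12 mm in any direction", {
  expect_true(endpoint_trigger(12, 5))
  expect_false(endpoint_trigger(11.9, 11.9))
  expect_false(endpoint_trigger(0, 0))
  expect_true(endpoint_trigger(5, 13)) # either axis
})

test_that("response classification distinguishes durable, recurrent, progressive", {
  days <- c(0, 7, 14, 16, 18, 25, 32, 39)
  # eradicated at +2 d and stays at zero
  vol_dur <- c(5, 50, 120, 0, 0, 0, 0, 0)
  r <- classify_response(days, vol_dur, treatment_day = 14)
  expect_identical(r$label, "eradicated_durable")
  expect_true(is.na(r$progression_day))
  # eradicated then recurs
  vol_rec <- c(5, 50, 120, 0, 0, 0, 3, 20)
  r2 <- classify_response(days, vol_rec, treatment_day = 14)
  expect_identical(r2$label, "eradicated_recurrent")
  expect_identical(r2$progression_day, 32)
  # monotone growth progresses at the first post-treatment increase
  vol_pro <- c(5, 50, 120, 150, 180, 240, 300, 400)
  r3 <- classify_response(days, vol_pro, treatment_day = 14)
  expect_identical(r3$label, "stable_or_progressive")
  expect_identical(r3$progression_day, 16)
  expect_error(classify_response(c(0, 7), c(5, 120), treatment_day = 14),
               "post-treatment")
})

test_that("KM estimate matches a hand-computed product-limit table", {
  # 6 subjects: events at 1, 2, 2, 4; censored at 3 and 5
  # S(1) = 5/6; S(2) = 5/6 * 3/5 = 1/2; S(4) = 1/2 * 1/2 = 1/4
  km <- km_estimate(c(1, 2, 2, 3, 4, 5), c(1, 1, 1, 0, 1, 0))
  expect_equal(km$time, c(0, 1, 2, 3, 4, 5))
  expect_equal(km$survival, c(1, 5 / 6, 1 / 2, 1 / 2, 1 / 4, 1 / 4))
  expect_equal(km$n_risk, c(6, 6, 5, 3, 2, 1))
  expect_equal(km$n_event, c(0, 1, 2, 0, 1, 0))
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(21)
  for (rep in 1:5) {
    t_ <- sample(1:20, 12, replace = TRUE)
    km <- km_estimate(t_, rep(1, 12))
    for (i in seq_len(nrow(km)))
      expect_equal(km$survival[i], mean(t_ > km$time[i]))
  }
})

test_that("all-censored input keeps survival at 1", {
  km <- km_estimate(c(3, 9, 14), c(0, 0, 0))
  expect_true(all(km$survival == 1))
})

test_that("events at 1 and 2 with n = 2 halve then zero the curve", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(1, 0.5, 0))
})

test_that("log-rank statistic matches direct formula evaluation", {
  # independent oracle: accumulate observed-minus-expected and the
  # hypergeometric variance over distinct event times
  logrank_direct <- function(t1, e1, t2, e2) {
    times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
    O_E <- 0; V <- 0
    for (tt in times) {
      n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
      d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
      d <- d1 + d2
      O_E <- O_E + d1 - d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    }
    O_E^2 / V
  }
  t1 <- c(2, 4, 5, 7, 9); e1 <- c(1, 1, 0, 1, 0)
  t2 <- c(1, 3, 3, 6, 8); e2 <- c(1, 1, 1, 1, 1)
  tab <- logrank_pairwise(c(t1, t2), c(e1, e2),
                          rep(c("A", "B"), each = 5), k_comparisons = 1)
  expect_equal(tab$statistic, logrank_direct(t1, e1, t2, e2),
               tolerance = 1e-10)
})

test_that("identical groups give statistic 0 and p = 1", {
  t_ <- c(1, 2, 3, 4); e <- c(1, 1, 0, 1)
  tab <- logrank_pairwise(c(t_, t_), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(tab$statistic, 0, tolerance = 1e-12)
  expect_equal(tab$p, 1)
})

test_that("Bonferroni correction multiplies and caps at 1", {
  expect_equal(bonferroni_adjust(0.01, 6), 0.06)
  expect_equal(bonferroni_adjust(0.3, 6), 1)
  expect_equal(bonferroni_adjust(c(0.001, 0.5), 4), c(0.004, 1))
})

test_that("four groups default to six pairwise comparisons", {
  coh <- gen_invivo_cohort(seed = 3)
  st <- survival_tables(coh$calipers, coh$subjects)
  tab <- logrank_pairwise(st$os_time, st$os_event, st$group)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$p_adjusted <= 1))
  expect_true(all(tab$p_adjusted >= tab$p))
})
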