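test_that("dose-response viability hits the anchor brackets and decreases", {
  m <- dose_response_model()
  v <- viability_at(c(0, 1000, 2000), m)
  expect_equal(v[1], 0.9499)                   # untreated baseline
  expect_gt(v[2], 0.1337); expect_lt(v[2], 0.5459)
  expect_gt(v[3], 0.0047); expect_lt(v[3], 0.0540)
  # strictly decreasing in field
  grid <- viability_at(seq(0, 3000, by = 50), m)
  expect_true(all(diff(grid) < 0))
  expect_error(dose_response_model(width = 0))
})

test_that("hydrogel lesion generation is deterministic and monotone in truth", {
  fm <- cached_hydrogel_field()
  l1 <- gen_hydrogel_lesions(500, n = 5, seed = 9, field = fm)
  l2 <- gen_hydrogel_lesions(500, n = 5, seed = 9, field = fm)
  expect_identical(l1$extent_mm, l2$extent_mm)
  expect_equal(length(unique(l1$extent_mm)), 5)
  # a tougher (higher-threshold) cell line leaves a smaller lesion
  hi <- gen_hydrogel_lesions(800, noise_cv = 0, n = 1, field = fm)
  lo <- gen_hydrogel_lesions(300, noise_cv = 0, n = 1, field = fm)
  expect_lt(hi$extent_mm, lo$extent_mm)
  # unattainable isocontours are rejected
  expect_error(gen_hydrogel_lesions(1e6, field = fm), "attainable")
})

test_that("spheroid generator honours its per-arm viability contracts", {
  ctrl <- track_frames(gen_spheroid_timelapse(0, FALSE, seed = 5))
  expect_true(all(abs(ctrl$normalized_green - (1 + 0.002 * ctrl$timepoint_h))
                  < 0.1))
  # sub-lethal field: rebound between 3 h and 72 h
  reb <- track_frames(gen_spheroid_timelapse(1000, FALSE, seed = 5))
  ng <- function(tr, t) tr$normalized_green[tr$timepoint_h == t]
  expect_gt(ng(reb, 72), ng(reb, 3))
  # adding CAR-T to the same field suppresses the rebound
  combo <- track_frames(gen_spheroid_timelapse(1500, TRUE, seed = 5))
  ire <- track_frames(gen_spheroid_timelapse(1500, FALSE, seed = 5))
  expect_lt(ng(combo, 72), ng(ire, 72))
  # determinism under the seed
  again <- track_frames(gen_spheroid_timelapse(1500, TRUE, seed = 5))
  expect_identical(combo$net_green, again$net_green)
})

test_that("net deep-red tracks the programmed infiltration fraction", {
  frames <- gen_spheroid_timelapse(0, TRUE, seed = 8)
  met <- do.call(rbind, lapply(frames, frame_metrics))
  # programmed infiltration at t >= 3: 0.1 + 0.5 * (t - 3) / 69
  f <- function(t) 0.1 + 0.5 * (t - 3) / 69
  r24 <- met$net_deepred[met$timepoint_h == 24]
  r72 <- met$net_deepred[met$timepoint_h == 72]
  expect_equal(r72 / r24, f(72) / f(24), tolerance = 0.05)
})

test_that("spheroid swelling grows with the applied field", {
  a1 <- track_frames(gen_spheroid_timelapse(1000, FALSE, seed = 2))
  a2 <- track_frames(gen_spheroid_timelapse(2500, FALSE, seed = 2))
  expect_gt(a2$normalized_area[a2$timepoint_h == 3],
            a1$normalized_area[a1$timepoint_h == 3])
  expect_gt(a1$normalized_area[a1$timepoint_h == 3], 1)
})

test_that("cohort generator honours its group contracts", {
  coh <- gen_invivo_cohort(seed = 17)
  s <- coh$subjects
  expect_equal(nrow(s), 24)
  # combination arm never recurs; IRE and combination always eradicate
  expect_true(all(s$programmed_label[s$group == "combination"] ==
                    "eradicated_durable"))
  expect_true(all(s$programmed_label[s$group %in% c("sham", "CAR-T")] ==
                    "stable_or_progressive"))
  # eradication within 48 h: first measurement at/after +2 d is zero
  for (i in which(s$group %in% c("IRE", "combination"))) {
    cal <- coh$calipers[coh$calipers$animal_id == s$animal_id[i], ]
    post <- cal[cal$day >= s$treatment_day[i] + 2, ]
    if (nrow(post) > 0) expect_equal(tumor_volume(post$length_mm[1],
                                                  post$width_mm[1]), 0)
  }
  # determinism
  expect_identical(gen_invivo_cohort(seed = 17)$calipers, coh$calipers)
})

test_that("IRE-arm recurrence frequency matches its binomial expectation", {
  nrec <- vapply(1:200, function(s)
    sum(gen_invivo_cohort(seed = s)$subjects$programmed_label ==
          "eradicated_recurrent"), numeric(1))
  # 200 seeds x Binomial(6, 4/6): mean within 4 SEs of 4
  se <- sqrt(6 * (4 / 6) * (2 / 6) / 200)
  expect_lt(abs(mean(nrec) - 4), 4 * se)
})

test_that("sham animals progress before the end of follow-up", {
  for (s in c(1, 2, 3)) {
    coh <- gen_invivo_cohort(seed = s)
    st <- survival_tables(coh$calipers, coh$subjects)
    expect_true(all(st$pfs_event[st$group == "sham"] == 1))
  }
})
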