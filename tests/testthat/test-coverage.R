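test_that("spacing rule is 1 mm below the maximum tumor diameter", {
  expect_identical(spacing_rule(6), 5)
  expect_identical(spacing_rule(4), 3)
  expect_identical(spacing_rule(8), 7)
  expect_error(spacing_rule(1), "exceed 1 mm")
})

test_that("scenario sampling respects ranges, the seed, and degenerate input", {
  th <- threshold_estimate(525, 77, 442, 613)
  sc <- sample_scenarios(30, th, seed = 7)
  expect_equal(nrow(sc), 30)
  expect_true(all(sc$tumor_diameter >= 4 & sc$tumor_diameter <= 8))
  expect_true(all(sc$threshold >= 442 & sc$threshold <= 613))
  expect_equal(sc$spacing, sc$tumor_diameter - 1)
  expect_identical(sample_scenarios(30, th, seed = 7), sc)

  th0 <- threshold_estimate(500, 0, 500, 500)
  sc0 <- sample_scenarios(5, th0, seed = 1)
  expect_true(all(sc0$threshold == 500))
  scf <- sample_scenarios(5, th, seed = 1, threshold_fixed = TRUE)
  expect_true(all(scf$threshold == 525))
  scw <- sample_scenarios(5, th, seed = 1, threshold_fixed = "worst_case")
  expect_true(all(scw$threshold == 613))

  bad <- planning_ranges(); bad$tumor_diameter <- c(8, 4)
  expect_error(sample_scenarios(5, th, ranges = bad, seed = 1), "degenerate")
})

test_that("coverage counts the tumor voxels at or above threshold", {
  labels <- array(0L, c(4, 4, 1))
  labels[1:2, , 1] <- 1L  # 8 tumor voxels
  mag <- array(0, c(4, 4, 1))
  mag[1, , 1] <- 600     # exactly half the tumor voxels above threshold
  dom <- make_synthetic_domain(labels)
  fm <- make_synthetic_field(mag)
  expect_equal(compute_coverage(fm, dom, 500), 0.5)
  expect_equal(compute_coverage(fm, dom, 0), 1)
  expect_equal(compute_coverage(fm, dom, 1e6), 0)
  empty <- make_synthetic_domain(array(0L, c(4, 4, 1)))
  expect_error(compute_coverage(fm, empty, 500), "tumor")
})

test_that("per-scenario coverage is monotone in ratio and threshold", {
  th <- threshold_estimate(525, 77, 442, 613)
  sc <- sample_scenarios(3, th, seed = 3)
  res <- run_plan(sc, resolution = 0.5)
  for (id in unique(res$table$scenario_id)) {
    cov <- res$table$coverage[res$table$scenario_id == id]
    expect_true(all(diff(cov) >= 0))
  }
  # same scenarios, higher thresholds: coverage can only drop
  sc_hi <- sc; sc_hi$threshold <- sc$threshold + 200
  res_hi <- run_plan(sc_hi, resolution = 0.5)
  expect_true(all(res_hi$table$coverage <= res$table$coverage + 1e-12))
})

test_that("zero threshold and extreme ratios give complete coverage", {
  th0 <- threshold_estimate(500, 0, 500, 500)
  sc <- sample_scenarios(1, th0, seed = 2)
  sc$threshold <- 0
  res <- run_plan(sc, candidate_ratios = c(1000, 3000), resolution = 0.5)
  expect_true(all(res$table$coverage == 1))
  # any finite threshold is exceeded everywhere as ratio grows
  sc2 <- sample_scenarios(1, threshold_estimate(525, 77, 442, 613), seed = 2)
  res2 <- run_plan(sc2, candidate_ratios = c(1000, 10000), resolution = 0.5)
  expect_equal(res2$table$coverage[res2$table$ratio == 10000], 1)
})

test_that("coverage is invariant to a global conductivity rescaling", {
  th <- threshold_estimate(525, 77, 442, 613)
  sc <- sample_scenarios(1, th, seed = 5)
  sc_k <- sc
  sc_k$tumor_conductivity <- 10 * sc$tumor_conductivity
  sc_k$background_conductivity <- 10 * sc$background_conductivity
  res <- run_plan(sc, resolution = 0.5)
  res_k <- run_plan(sc_k, resolution = 0.5)
  expect_equal(res_k$table$coverage, res$table$coverage)
})

test_that("select_dose equals a brute-force scan of the coverage table", {
  brute <- function(result) {
    ratios <- sort(unique(result$table$ratio))
    for (r in ratios)
      if (all(result$table$coverage[result$table$ratio == r] >= 1)) return(r)
    ratios[length(ratios)]
  }
  fake_result <- function(cov_matrix, ratios) {
    tab <- data.frame(
      scenario_id = rep(seq_len(nrow(cov_matrix)), each = length(ratios)),
      ratio = rep(ratios, nrow(cov_matrix)),
      coverage = as.numeric(t(cov_matrix)))
    structure(list(table = tab,
                   scenarios = data.frame(spacing = rep(5, nrow(cov_matrix)))),
              class = "coverage_result")
  }
  ratios <- c(1000, 1500, 2000, 2500, 3000)
  cases <- list(
    matrix(1, 2, 5),                                    # complete everywhere
    rbind(c(0.8, 0.9, 1, 1, 1), c(0.7, 0.95, 1, 1, 1)), # first at the middle
    rbind(c(0.8, 0.9, 0.95, 0.99, 1), c(0.7, 0.8, 0.9, 0.95, 0.99)))
  for (cm in cases) {
    res <- fake_result(cm, ratios)
    dp <- select_dose(res)
    expect_identical(dp$selected_ratio, brute(res))
  }
  # incomplete case is flagged
  dp3 <- select_dose(fake_result(cases[[3]], ratios))
  expect_false(dp3$complete)
  dp2 <- select_dose(fake_result(cases[[2]], ratios))
  expect_true(dp2$complete)
  expect_identical(dp2$selected_ratio, 2000)
})

test_that("candidate ratios must be positive and ascending", {
  th <- threshold_estimate(525, 77, 442, 613)
  sc <- sample_scenarios(1, th, seed = 1)
  expect_error(run_plan(sc, candidate_ratios = c(3000, 1000)))
  expect_error(run_plan(sc, candidate_ratios = c(-1, 1000)))
})
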