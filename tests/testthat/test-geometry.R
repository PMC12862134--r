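test_that("rasterized tumor volume matches the analytic sphere volume", {
  el <- electrode_config(spacing = 5, applied_voltage = 1250)
  dom <- build_domain(6, c(0.2, 0.1), el, resolution = 0.25)
  # voxels inside the tumor radius (whatever their label; the needles carve
  # electrode voxels out of the tumor label where they pass through it)
  r2 <- outer(outer(dom$coords$x^2, dom$coords$y^2, `+`), dom$coords$z^2, `+`)
  inside <- sum(r2 <= 3^2)
  analytic <- (pi / 6) * 6^3 / 0.25^3
  expect_lt(abs(inside - analytic) / analytic, 0.05)
  # tumor-labeled voxels = sphere voxels minus the electrode overlap
  overlap <- sum(dom$labels[r2 <= 3^2] %in% c(2L, 3L))
  expect_identical(sum(dom$labels == 1L), inside - overlap)
})

test_that("small tumors sit strictly inside a valid domain", {
  el <- electrode_config(spacing = 8, applied_voltage = 100)
  dom <- build_domain(0.5, c(0.2, 0.1), el, resolution = 0.5,
                      extent = c(40, 40, 40))
  tm <- tumor_mask(dom)
  expect_gt(sum(tm), 0)
  idx <- which(tm, arr.ind = TRUE)
  expect_true(all(idx > 1) && all(t(idx) < dom$dims))
})

test_that("invalid geometries are rejected", {
  expect_error(electrode_config(spacing = 5, applied_voltage = 100,
                                electrode_radius = 3),
               "overlapping")
  el <- electrode_config(spacing = 5, applied_voltage = 100)
  expect_error(build_domain(25, c(0.2, 0.1), el, resolution = 0.5),
               "larger than domain")
  expect_error(build_domain(4, c(0.2, 0.1), el, resolution = 0.8),
               "coarser")
  expect_error(build_domain(4, c(0.2, -0.1), el, resolution = 0.5),
               "positive")
  expect_error(build_domain(4, c(0.2, 0.1), el, resolution = 0.5,
                            extent = c(10, 10, 10)),
               "4x")
})

test_that("parallel plates produce two full-face electrode slabs", {
  el <- electrode_config(mode = "parallel_plate", spacing = 8.5,
                        applied_voltage = 400)
  dom <- build_domain(0, 1.4, el, resolution = 0.5)
  expect_gt(sum(dom$labels == 2L), 0)
  expect_gt(sum(dom$labels == 3L), 0)
  # plus slab occupies entire yz planes
  plus_x <- apply(dom$labels == 2L, 1, any)
  expect_true(all(apply(dom$labels[plus_x, , , drop = FALSE] == 2L,
                        1, all)))
})

test_that("pulse scheme stores the conventional IRE protocol and validates", {
  ps <- pulse_scheme()
  expect_equal(ps$pulse_count, 90)
  expect_equal(ps$pulse_width_us, 90)
  expect_equal(ps$repetition_rate_hz, 1)
  expect_error(pulse_scheme(pulse_count = 0))
})

test_that("voltage-to-distance ratio is voltage over spacing in V/cm", {
  el <- electrode_config(spacing = 5, applied_voltage = 1250)
  expect_equal(voltage_distance_ratio(el), 2500)
})
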