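make_disk_image <- function(size = 256, radius = 80, peak = 180, bg = 20,
                            noise_sd = 3, seed = 1, center = NULL) {
  set.seed(seed)
  if (is.null(center)) center <- rep((size + 1) / 2, 2)
  d2 <- outer((seq_len(size) - center[1])^2, (seq_len(size) - center[2])^2, `+`)
  img <- matrix(bg + rnorm(size^2, 0, noise_sd), size, size)
  img[d2 <= radius^2] <- img[d2 <= radius^2] + peak
  pmax(img, 0)
}

test_that("segmentation recovers a synthetic disk to within 3% area", {
  img <- make_disk_image()
  mask <- segment_mcts(img)
  expect_false(attr(mask, "empty"))
  expect_lt(abs(sum(mask) - pi * 80^2) / (pi * 80^2), 0.03)
})

test_that("a constant image yields a flagged empty mask, not an error", {
  mask <- segment_mcts(matrix(7, 64, 64))
  expect_true(attr(mask, "empty"))
  expect_false(any(mask))
})

test_that("only the largest of two disks is retained", {
  img <- make_disk_image(size = 256, radius = 80, center = c(90, 90))
  d2 <- outer((1:256 - 200)^2, (1:256 - 200)^2, `+`)
  img[d2 <= 20^2] <- img[d2 <= 20^2] + 180
  mask <- segment_mcts(img)
  expect_lt(abs(sum(mask) - pi * 80^2) / (pi * 80^2), 0.05)
  # the small disk's center must not be in the mask
  expect_false(mask[200, 200])
})

test_that("segmentation is invariant to affine intensity rescaling", {
  img <- make_disk_image()
  m1 <- segment_mcts(img)
  m2 <- segment_mcts(3.7 * img + 55)
  expect_identical(m1, m2)
})

test_that("net intensity subtracts the background exactly", {
  # uniform image: net zero whatever the mask
  uni <- matrix(42, 128, 128)
  d2 <- outer((1:128 - 64.5)^2, (1:128 - 64.5)^2, `+`)
  mask <- d2 <= 30^2
  fr <- fluor_frame("w", 0, uni, pixel_size_um = 10)
  met <- frame_metrics(fr, mask)
  expect_equal(met$net_green, 0)
  # disk at 100 over background 10 -> net 90
  img <- matrix(10, 128, 128); img[mask] <- 100
  fr2 <- fluor_frame("w", 0, img, pixel_size_um = 10)
  met2 <- frame_metrics(fr2, mask)
  expect_equal(met2$net_green, 90)
  expect_equal(met2$area_mm2, sum(mask) * (10 / 1000)^2)
  # adding a constant offset leaves net intensity unchanged
  fr3 <- fluor_frame("w", 0, img + 500, pixel_size_um = 10)
  expect_equal(frame_metrics(fr3, mask)$net_green, 90)
})

test_that("an empty mask is flagged with zero area and undefined intensities", {
  fr <- fluor_frame("w", 0, matrix(5, 32, 32))
  met <- frame_metrics(fr, matrix(FALSE, 32, 32))
  expect_true(met$empty)
  expect_identical(met$area_mm2, 0)
  expect_true(is.na(met$net_green))
})

test_that("track normalization divides by the pre-treatment baseline", {
  met <- data.frame(well_id = "w", timepoint_h = c(0, 3, 72),
                    area_mm2 = c(2, 2, 2),
                    mean_green_inside = NA, mean_green_background = NA,
                    net_green = c(100, 100, 100), net_deepred = 0,
                    empty = FALSE)
  tr <- normalize_track(met)
  expect_equal(tr$normalized_green, c(1, 1, 1))
  expect_equal(tr$normalized_area, c(1, 1, 1))
  met$net_green <- c(100, 50, 80)
  tr2 <- normalize_track(met)
  expect_equal(tr2$normalized_green, c(1, 0.5, 0.8))
  met$net_green[1] <- 0
  expect_error(normalize_track(met), "baseline")
  expect_error(normalize_track(met[1, ]))
})

test_that("XTT normalization applies the reference-wavelength correction", {
  rec <- xtt_normalize(0.9, 0.1, control_mean = 0.8)
  expect_equal(rec$normalized_absorbance, 0.8)
  expect_equal(rec$fold_of_control, 1)
  expect_equal(xtt_normalize(0.37, 0.37, 1)$normalized_absorbance, 0)
  # a batch of control wells self-normalizes to mean fold 1
  a475 <- c(0.8, 0.9, 1.0); a660 <- c(0.1, 0.15, 0.05)
  ctrl <- mean(a475 - a660)
  batch <- xtt_normalize(a475, a660, control_mean = ctrl)
  expect_equal(mean(batch$fold_of_control), 1)
  expect_error(xtt_normalize(0.9, 0.1, control_mean = 0), "positive")
  expect_error(xtt_normalize(-0.1, 0.1, control_mean = 1), "non-negative")
})
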