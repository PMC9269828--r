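test_that("level update follows the smoothing recursion exactly", {
  expect_equal(update_level(2, 5, 1), 5)    # alpha = 1 copies y
  expect_equal(update_level(2, 5, 0), 2)    # alpha = 0 keeps the level
  expect_equal(update_level(4, 10, 0.3), 5.8)
})

test_that("band update yields the smoothed-deviation band", {
  # alpha = 0.5, delta = 2, level_next = 5.8, y = 10, deviation = 1
  b <- update_band(5.8, 10, 1, 0.5, 2)
  expect_equal(b$deviation, 2.6)
  expect_equal(b$band_low, 0.6)
  expect_equal(b$band_high, 11.0)

  # constant series at its fixed point collapses the band
  b0 <- update_band(3, 3, 0, 0.4, 3)
  expect_equal(b0$deviation, 0)
  expect_equal(b0$band_low, 3)
  expect_equal(b0$band_high, 3)

  # alpha = 0 leaves the deviation unchanged
  expect_equal(update_band(5, 9, 0.7, 0, 2)$deviation, 0.7)
})

test_that("alarm triggers strictly above the forecast band", {
  cfg <- detector_config(alpha = 0.5, delta = 2, warmup = 1)
  state <- list(level = 5, deviation = 1, frame_count = 5L)
  # inside the band [3, 7]
  expect_false(score_frame(state, 6, cfg)$alarm)
  # exactly on the edge: no alarm (strict inequality)
  expect_false(score_frame(state, 7, cfg)$alarm)
  expect_true(score_frame(state, 7 + 1e-9, cfg)$alarm)
  # far above a tight band
  tight <- list(level = 1, deviation = 0.01, frame_count = 5L)
  expect_true(score_frame(tight, 10, cfg)$alarm)
  # lower-band excursions only alarm in two-sided mode
  expect_false(score_frame(state, 1, cfg)$alarm)
  cfg2 <- detector_config(alpha = 0.5, delta = 2, warmup = 1,
                          two_sided = TRUE)
  expect_true(score_frame(state, 1, cfg2)$alarm)
})

test_that("warm-up frames never alarm and the first observation initialises", {
  cfg <- detector_config(alpha = 0.3, delta = 2, warmup = 3)
  y <- c(1, 100, 100, 100, 100)
  res <- score_series(y, cfg)
  expect_false(any(res$alarm[1:3]))
  expect_equal(res$level[1], 1)       # level initialised to first y
  expect_true(all(res$band_low <= res$level & res$level <= res$band_high))
})

test_that("level recursion contracts geometrically on constant input", {
  alpha <- 0.3
  s <- 10
  errs <- numeric(20)
  for (i in 1:20) {
    s <- update_level(s, 2, alpha)
    errs[i] <- abs(s - 2)
  }
  expect_equal(errs, 8 * (1 - alpha)^(1:20))
})

test_that("the alarm set shrinks as delta grows", {
  set.seed(5)
  y <- abs(rnorm(60, 10, 1))
  y[c(25, 40)] <- c(30, 25)
  alarms <- lapply(c(2, 3, 5), function(d) {
    which(score_series(y, detector_config(delta = d))$alarm)
  })
  expect_true(all(alarms[[2]] %in% alarms[[1]]))
  expect_true(all(alarms[[3]] %in% alarms[[2]]))
  expect_gt(length(alarms[[1]]), 0)
})

test_that("alarms are invariant to a positive rescaling of the series", {
  set.seed(8)
  y <- abs(rnorm(50, 5, 0.5))
  y[30] <- 20
  cfg <- detector_config()
  a1 <- score_series(y, cfg)$alarm
  a2 <- score_series(y * 137.5, cfg)$alarm
  expect_identical(a1, a2)
})

test_that("detector config invariants are enforced", {
  expect_error(detector_config(alpha = 1.2), "alpha")
  expect_error(detector_config(delta = 1), "delta")
  expect_error(detector_config(warmup = 0), "warmup")
})

test_that("noiseless polyp-free straight scenes raise no alarms", {
  spec <- scene_spec(length_mm = 80, noise_sigma = 0, seed = 1)
  traj <- simulate_trajectory(spec)
  det <- run_detector(traj)
  expect_false(any(det$alarm))
  expect_true(all(det$y[-1] == 0))
})

test_that("a high-contrast polyp triggers alarms within its extent", {
  spec <- scene_spec(length_mm = 160,
                     polyps = data.frame(z_center_mm = 100, size_mm = 30),
                     seed = 4)
  traj <- simulate_trajectory(spec)
  det <- run_detector(traj)
  lesion <- traj$lesions[[1]]
  hits <- det$z_mm[det$alarm]
  expect_gt(length(hits), 0)
  step <- traj$step_mm
  inside <- hits < lesion$z_end_mm + step &
    (hits + step) > lesion$z_start_mm - step
  expect_true(any(inside))
})

test_that("delta sweep on a full trajectory nests the alarm sets", {
  spec <- scene_spec(length_mm = 120,
                     polyps = data.frame(z_center_mm = 75, size_mm = 25),
                     seed = 6)
  traj <- simulate_trajectory(spec)
  a2 <- which(run_detector(traj, detector_config(delta = 2))$alarm)
  a5 <- which(run_detector(traj, detector_config(delta = 5))$alarm)
  expect_true(all(a5 %in% a2))
})

test_that("too-short trajectories are rejected with the minimum length", {
  spec <- scene_spec(length_mm = 12, noise_sigma = 0, seed = 1)
  traj <- simulate_trajectory(spec)   # 4 frames < warmup + 2
  expect_error(run_detector(traj), "at least 5 frames")
})
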