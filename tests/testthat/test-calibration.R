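test_that("modified Hausdorff distance matches worked examples", {
  pts <- cbind(c(0, 1, 2), c(0, 1, 4))
  expect_equal(modified_hausdorff_distance(pts, pts), 0)
  expect_equal(modified_hausdorff_distance(cbind(0, 0), cbind(3, 4)), 5)
  # A = {(0,0),(1,0)}, B = {(0,1)}: max((1 + sqrt(2))/2, 1)
  a <- rbind(c(0, 0), c(1, 0)); b <- rbind(c(0, 1))
  expect_equal(modified_hausdorff_distance(a, b), (1 + sqrt(2)) / 2)
  expect_error(modified_hausdorff_distance(a[0, , drop = FALSE], b),
               "non-empty")
})

test_that("mhd agrees with a brute-force oracle on random point sets", {
  set.seed(101)
  for (rep in 1:50) {
    a <- matrix(rnorm(2 * sample(1:30, 1)), ncol = 2)
    b <- matrix(rnorm(2 * sample(1:30, 1)), ncol = 2)
    expect_equal(modified_hausdorff_distance(a, b), mhd_oracle(a, b))
    expect_equal(modified_hausdorff_distance(a, b),
                 modified_hausdorff_distance(b, a))
  }
})

test_that("frame distances are symmetric, zero on identity, and exact on
           single-pair perturbations", {
  set.seed(7)
  f <- random_frame(0L)
  expect_equal(frame_distance(f, f, "mhd"), 0)
  expect_equal(frame_distance(f, f, "chebyshev"), 0)

  g <- f
  g$values[5] <- g$values[5] + 0.25
  expect_equal(frame_distance(f, g, "chebyshev"), 0.25)

  h <- random_frame(1L)
  expect_equal(frame_distance(f, h, "mhd"), frame_distance(h, f, "mhd"))
  expect_equal(frame_distance(f, h, "mhd"),
               mhd_oracle(cbind(Re(f$values), Im(f$values)),
                          cbind(Re(h$values), Im(h$values))))

  small <- sparam_frame(0, 0, rep(0i, 9),
                        build_measurement_plan(array_geometry(3)))
  expect_error(frame_distance(f, small), "plan")
})

test_that("reference selection minimises the distance with recency ties", {
  set.seed(21)
  cur <- random_frame(5L)

  # exact copy in the pool -> selected at distance zero
  copy <- cur; copy$frame_index <- 2L
  pool <- list(random_frame(0L), copy, random_frame(3L))
  expect_identical(select_reference(cur, pool)$frame_index, 2L)

  # constructed distances 3, 1, 2 (single-pair chebyshev offsets)
  mk <- function(eps, idx) {
    g <- cur; g$frame_index <- idx
    g$values[1] <- g$values[1] + eps
    g
  }
  pool <- list(mk(3, 0L), mk(1, 1L), mk(2, 2L))
  expect_identical(select_reference(cur, pool, "chebyshev")$frame_index, 1L)

  # argmin under mhd agrees with a brute-force scan of the pool
  pool2 <- list(random_frame(0L), random_frame(1L), random_frame(2L))
  d <- sapply(pool2, function(g) frame_distance(cur, g, "mhd"))
  expect_identical(select_reference(cur, pool2, "mhd")$frame_index,
                   pool2[[which.min(d)]]$frame_index)

  # tie broken towards the most recent frame
  tie <- list(mk(1, 0L), mk(1, 3L))
  expect_identical(select_reference(cur, tie, "chebyshev")$frame_index, 3L)

  expect_error(select_reference(cur, list()), "no reference")
  late <- random_frame(9L)
  expect_error(select_reference(cur, list(late)), "earlier")
})

test_that("calibration subtracts exactly", {
  set.seed(3)
  f <- random_frame(4L)
  self <- calibrate(f, f)
  expect_equal(unname(self$values), rep(0 + 0i, 24))

  delta <- complex(real = rnorm(24), imaginary = rnorm(24))
  g <- f
  g$values <- g$values + delta
  g$frame_index <- 5L
  cal <- calibrate(g, f)
  expect_equal(unname(cal$values), delta)
  expect_identical(cal$reference_index, 4L)
})

test_that("stationary noiseless scenes calibrate to the exact zero field,
           polyp frames do not", {
  spec <- scene_spec(length_mm = 120,
                     polyps = data.frame(z_center_mm = 80, size_mm = 30),
                     noise_sigma = 0, seed = 1)
  traj <- simulate_trajectory(spec)
  cal <- calibrate_trajectory(traj)
  expect_null(cal[[1]])
  z <- frame_z(traj)
  energy <- sapply(cal[-1], calibrated_energy)
  # far from the lesion the residual is only the vanishing axial tail
  far <- z[-1] < 40
  expect_true(all(energy[far] < 1e-20))
  # entering the lesion leaves a large residual; deeper frames may cancel
  # against earlier lesion frames, which is how the alarm is meant to work
  over <- z[-1] >= 66 & z[-1] <= 94
  expect_gt(max(energy[over]), 1)

  # without a polyp the cancellation is exact
  clean <- simulate_trajectory(scene_spec(length_mm = 60, noise_sigma = 0,
                                          seed = 1))
  cal0 <- calibrate_trajectory(clean)
  expect_true(all(sapply(cal0[-1], calibrated_energy) == 0))
})

test_that("temporal calibration beats first-frame subtraction on curved
           scenes", {
  spec <- scene_spec(length_mm = 100, curve_amplitude_mm = 3,
                     curve_period_mm = 200, curve_angle_rad = pi / 3,
                     noise_sigma = 0, seed = 1)
  traj <- simulate_trajectory(spec)
  m <- frame_matrix(traj)
  cal <- calibrate_trajectory(traj)
  at_energy <- sum(sapply(cal[-1], calibrated_energy))
  first_energy <- sum(sapply(2:nrow(m), function(i) {
    sum(Mod(m[i, ] - m[1, ])^2)
  }))
  expect_lt(at_energy, first_energy)
})

test_that("a window-limited pool only uses recent frames", {
  spec <- scene_spec(length_mm = 60, curve_amplitude_mm = 3,
                     curve_period_mm = 120, noise_sigma = 0, seed = 2)
  traj <- simulate_trajectory(spec)
  cal <- calibrate_trajectory(traj, pool_window = 2)
  for (i in seq_along(cal)[-1]) {
    expect_gte(cal[[i]]$reference_index, cal[[i]]$frame_index - 2L)
  }
})
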