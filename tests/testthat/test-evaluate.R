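# forge a detection result with a prescribed alarm set
forged_detection <- function(traj, alarm_frames, warmup = 3) {
  n <- length(traj$frames)
  out <- data.frame(frame_index = 0:(n - 1L), z_mm = frame_z(traj),
                    reference_index = NA_integer_, y = NA_real_,
                    level = NA_real_, band_low = NA_real_,
                    band_high = NA_real_,
                    alarm = (0:(n - 1L)) %in% alarm_frames)
  attr(out, "config") <- detector_config(warmup = warmup)
  class(out) <- c("mw_detection", "data.frame")
  out
}

lesion_traj <- function(length_mm = 200, z_start = 84, z_end = 116) {
  spec <- scene_spec(length_mm = length_mm, noise_sigma = 0, seed = 1)
  traj <- simulate_trajectory(spec)
  traj$lesions <- list(lesion_truth(z_start, z_end, "adenocarcinoma"))
  traj
}

test_that("frames are labelled by dilated interval intersection", {
  traj <- lesion_traj()
  lab0 <- label_frames(traj, tolerance_frames = 0)
  expect_equal(lab0$frame_index[lab0$label == "lesion"], 21:28)
  lab1 <- label_frames(traj, tolerance_frames = 1)
  expect_equal(lab1$frame_index[lab1$label == "lesion"], 20:29)
  expect_false(any(lab1$scored[1:4]))   # frame 0 + 3 warm-up frames
  expect_true(all(lab1$scored[5:length(lab1$scored)]))

  healthy <- simulate_trajectory(scene_spec(length_mm = 40,
                                            noise_sigma = 0, seed = 1))
  expect_true(all(label_frames(healthy)$label == "healthy"))

  outside <- traj
  outside$lesions <- list(lesion_truth(300, 340, "adenocarcinoma"))
  expect_error(label_frames(outside), "outside the trajectory")
})

test_that("confusion counting uses lesion-level positives and frame-level
           negatives", {
  traj <- lesion_traj()                 # 51 frames, lesion frames 20..29
  scored <- 4:50

  # perfect detection: alarms only inside the lesion
  det <- forged_detection(traj, c(23, 24))
  cc <- confusion_counts(det, traj)
  expect_equal(cc$tp, 1L); expect_equal(cc$fn, 0L); expect_equal(cc$fp, 0L)
  expect_equal(cc$tn, length(setdiff(scored, 20:29)))

  # total miss
  cc0 <- confusion_counts(forged_detection(traj, integer(0)), traj)
  expect_equal(cc0$tp, 0L); expect_equal(cc0$fn, 1L)
  expect_equal(cc0$fp, 0L)
  expect_equal(cc0$tn, length(setdiff(scored, 20:29)))

  # detected lesion plus two healthy-frame alarms
  cc2 <- confusion_counts(forged_detection(traj, c(10, 24, 40)), traj)
  expect_equal(cc2$tp, 1L); expect_equal(cc2$fp, 2L)
  expect_equal(cc2$tn, length(setdiff(scored, 20:29)) - 2L)

  # frame-level positive unit instead
  ccf <- confusion_counts(forged_detection(traj, c(23, 24)), traj,
                          positive_unit = "frame")
  expect_equal(ccf$tp, 2L)
  expect_equal(ccf$fn, 8L)
})

test_that("sensitivity and specificity follow the exact percentage formula", {
  ss <- sensitivity_specificity(list(tp = 15, fn = 0, tn = 0, fp = 0))
  expect_equal(ss[["sensitivity"]], 100)
  expect_true(is.na(ss[["specificity"]]))

  ss2 <- sensitivity_specificity(list(tp = 0, fn = 0, tn = 16, fp = 1))
  expect_equal(round(ss2[["specificity"]], 2), 94.12)
  expect_true(is.na(ss2[["sensitivity"]]))
})

test_that("counting units are conserved across detector configurations", {
  spec <- scene_spec(length_mm = 120,
                     polyps = data.frame(z_center_mm = 75, size_mm = 25),
                     seed = 12)
  traj <- simulate_trajectory(spec)
  counts <- lapply(c(2, 4), function(d) {
    det <- run_detector(traj, detector_config(delta = d))
    confusion_counts(det, traj)
  })
  expect_equal(counts[[1]]$tp + counts[[1]]$fn,
               counts[[2]]$tp + counts[[2]]$fn)
  expect_equal(counts[[1]]$tn + counts[[1]]$fp,
               counts[[2]]$tn + counts[[2]]$fp)
  lab <- label_frames(traj)
  expect_equal(counts[[1]]$tn + counts[[1]]$fp,
               sum(lab$scored & lab$label == "healthy"))
})

test_that("ensemble evaluation pools counts and preserves single-trajectory
           results", {
  spec <- scene_spec(length_mm = 120,
                     polyps = data.frame(z_center_mm = 75, size_mm = 25),
                     seed = 13)
  traj <- simulate_trajectory(spec, label = "solo")
  rep1 <- evaluate_ensemble(list(traj))
  expect_equal(rep1$overall$counts$tp, rep1$per_trajectory$tp[1])
  expect_equal(rep1$overall$sensitivity, rep1$per_trajectory$sensitivity[1])

  spec2 <- scene_spec(length_mm = 100,
                      polyps = data.frame(z_center_mm = 60, size_mm = 30),
                      seed = 14)
  traj2 <- simulate_trajectory(spec2, label = "second")
  rep2 <- evaluate_ensemble(list(traj, traj2))
  expect_equal(rep2$overall$counts$tp, sum(rep2$per_trajectory$tp))
  expect_equal(rep2$overall$counts$fp, sum(rep2$per_trajectory$fp))
  expect_equal(rep2$overall$counts$tn, sum(rep2$per_trajectory$tn))
  expect_equal(rep2$overall$counts$fn, sum(rep2$per_trajectory$fn))
})

test_that("sensitivity and specificity move oppositely along a delta sweep", {
  specs <- list(
    scene_spec(length_mm = 120,
               polyps = data.frame(z_center_mm = 75, size_mm = 20),
               seed = 15),
    scene_spec(length_mm = 100,
               polyps = data.frame(z_center_mm = 60, size_mm = 14),
               curve_amplitude_mm = 3, curve_period_mm = 200, seed = 16))
  trajs <- lapply(specs, simulate_trajectory)
  sweep <- lapply(c(2, 3, 6), function(d) {
    evaluate_ensemble(trajs, detector_config(delta = d))$overall
  })
  sens <- sapply(sweep, `[[`, "sensitivity")
  specp <- sapply(sweep, `[[`, "specificity")
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(specp) >= 0))
})
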