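#' Label frames from lesion ground truth
#'
#' A frame covers the axial interval `[z_n, z_n + step)`. It is labelled
#' `"lesion"` when that interval intersects any ground-truth lesion extent
#' dilated by `tolerance_frames * step` on each side, `"healthy"` otherwise.
#' Frame 0 (never calibrated) and the detector warm-up frames are marked as
#' not scored and are excluded from performance counting.
#'
#' @param traj An `mw_trajectory` with lesion ground truth.
#' @param tolerance_frames Dilation of each lesion extent in frames, to
#'   absorb the registration uncertainty of manually located lesions.
#'   Default 1.
#' @param warmup Number of warm-up frames after frame 0 (matching the
#'   detector configuration). Default 3.
#' @return Data frame with columns `frame_index`, `z_mm`, `label`
#'   (`"lesion"`/`"healthy"`) and `scored` (logical).
#' @export
label_frames <- function(traj, tolerance_frames = 1, warmup = 3) {
  stopifnot(inherits(traj, "mw_trajectory"))
  z <- frame_z(traj)
  step <- traj$step_mm
  z_lo <- min(z); z_hi <- max(z) + step
  for (l in traj$lesions) {
    if (l$z_end_mm <= z_lo || l$z_start_mm >= z_hi) {
      stop(sprintf("lesion [%g, %g] mm lies outside the trajectory",
                   l$z_start_mm, l$z_end_mm), call. = FALSE)
    }
  }
  tol <- tolerance_frames * step
  lesion <- rep(FALSE, length(z))
  for (l in traj$lesions) {
    lesion <- lesion |
      (z < l$z_end_mm + tol & (z + step) > l$z_start_mm - tol)
  }
  idx <- seq_along(z) - 1L
  data.frame(frame_index = idx, z_mm = z,
             label = ifelse(lesion, "lesion", "healthy"),
             scored = idx > warmup)
}

#' Confusion counts from a detection result
#'
#' Uses a hybrid counting unit: each ground-truth lesion is one positive
#' unit (true positive when at least one alarm frame overlaps its dilated
#' extent, false negative otherwise), while each scored healthy frame is one
#' negative unit (false positive when it alarms, true negative otherwise).
#' Set `positive_unit = "frame"` to count every scored lesion frame as a
#' positive unit instead.
#'
#' @param result An `mw_detection` from [run_detector()].
#' @param traj The trajectory the result was computed on.
#' @param tolerance_frames Lesion-extent dilation in frames. Default 1.
#' @param positive_unit `"lesion"` (default) or `"frame"`.
#' @param warmup Warm-up frames; defaults to the config stored in `result`.
#' @return An object of class `mw_confusion`: list with integer `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(result, traj, tolerance_frames = 1,
                             positive_unit = c("lesion", "frame"),
                             warmup = NULL) {
  stopifnot(inherits(result, "mw_detection"),
            inherits(traj, "mw_trajectory"))
  positive_unit <- match.arg(positive_unit)
  if (is.null(warmup)) {
    cfg <- attr(result, "config")
    warmup <- if (!is.null(cfg)) cfg$warmup else 3L
  }
  if (nrow(result) != length(traj$frames)) {
    stop("detection result and trajectory cover different frame sets",
         call. = FALSE)
  }
  labels <- label_frames(traj, tolerance_frames, warmup)
  scored <- labels$scored
  alarm <- result$alarm

  step <- traj$step_mm
  tol <- tolerance_frames * step
  alarm_z <- result$z_mm[alarm & scored]

  if (positive_unit == "lesion") {
    tp <- 0L; fn <- 0L
    for (l in traj$lesions) {
      hit <- any(alarm_z < l$z_end_mm + tol &
                 (alarm_z + step) > l$z_start_mm - tol)
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    }
  } else {
    pos <- scored & labels$label == "lesion"
    tp <- sum(pos & alarm)
    fn <- sum(pos & !alarm)
  }
  neg <- scored & labels$label == "healthy"
  fp <- sum(neg & alarm)
  tn <- sum(neg & !alarm)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "mw_confusion")
}

#' @export
print.mw_confusion <- function(x, ...) {
  cat(sprintf("<mw_confusion> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = 100 * TP / (TP + FN)` and
#' `specificity = 100 * TN / (TN + FP)`. A zero denominator yields `NA`
#' (undefined), never a silent 0 or 100.
#'
#' @param counts An `mw_confusion` (or list with `tp`, `fp`, `tn`, `fn`).
#' @return Named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
sensitivity_specificity <- function(counts) {
  sens <- if (counts$tp + counts$fn > 0) {
    100 * counts$tp / (counts$tp + counts$fn)
  } else NA_real_
  spec <- if (counts$tn + counts$fp > 0) {
    100 * counts$tn / (counts$tn + counts$fp)
  } else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Evaluate the pipeline over an ensemble of trajectories
#'
#' Runs the full calibrate-reconstruct-detect pipeline on each trajectory,
#' counts lesion-level positives and frame-level negatives, and reports
#' per-trajectory and pooled (micro-averaged) sensitivity and specificity;
#' macro averages of the per-trajectory percentages are reported alongside.
#'
#' @param trajs List of `mw_trajectory` objects (each with ground truth).
#' @param config An [detector_config()].
#' @param tolerance_frames Lesion-extent dilation in frames. Default 1.
#' @param positive_unit Passed to [confusion_counts()].
#' @param ... Further arguments passed to [run_detector()] (metric, grid,
#'   `field_power`, `pool_window`).
#' @return An object of class `mw_report`: list with `per_trajectory` (data
#'   frame: label, histology, lesion size, length, counts, percentages) and
#'   `overall` (pooled counts plus micro and macro percentages).
#' @export
evaluate_ensemble <- function(trajs, config = detector_config(),
                              tolerance_frames = 1,
                              positive_unit = c("lesion", "frame"), ...) {
  positive_unit <- match.arg(positive_unit)
  stopifnot(length(trajs) >= 1)
  rows <- vector("list", length(trajs))
  pooled <- list(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_along(trajs)) {
    traj <- trajs[[i]]
    det <- run_detector(traj, config = config, ...)
    cc <- confusion_counts(det, traj, tolerance_frames, positive_unit)
    ss <- sensitivity_specificity(cc)
    first <- if (length(traj$lesions) > 0) traj$lesions[[1]] else NULL
    rows[[i]] <- data.frame(
      label = traj$label,
      histology = if (is.null(first)) NA_character_ else
        first$histology_label,
      lesion_size_mm = if (is.null(first)) NA_real_ else first$size_mm,
      length_mm = max(frame_z(traj)) - min(frame_z(traj)),
      tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
      sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]])
    pooled$tp <- pooled$tp + cc$tp; pooled$fp <- pooled$fp + cc$fp
    pooled$tn <- pooled$tn + cc$tn; pooled$fn <- pooled$fn + cc$fn
  }
  per <- do.call(rbind, rows)
  overall <- sensitivity_specificity(pooled)
  structure(list(
    per_trajectory = per,
    overall = list(
      counts = pooled,
      sensitivity = overall[["sensitivity"]],
      specificity = overall[["specificity"]],
      macro_sensitivity = mean(per$sensitivity, na.rm = TRUE),
      macro_specificity = mean(per$specificity, na.rm = TRUE))),
    class = "mw_report")
}

#' @export
print.mw_report <- function(x, ...) {
  df <- x$per_trajectory
  df$sensitivity <- sprintf("%.2f", df$sensitivity)
  df$specificity <- sprintf("%.2f", df$specificity)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf(
    "overall (pooled): sensitivity %.2f%%, specificity %.2f%% (TP=%d FP=%d TN=%d FN=%d)\n",
    x$overall$sensitivity, x$overall$specificity, x$overall$counts$tp,
    x$overall$counts$fp, x$overall$counts$tn, x$overall$counts$fn))
  cat(sprintf("overall (macro): sensitivity %.2f%%, specificity %.2f%%\n",
              x$overall$macro_sensitivity, x$overall$macro_specificity))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' @param report An `mw_report`.
#' @param path Output CSV path; the pooled overall row is appended with
#'   label `"overall"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mw_report"))
  df <- report$per_trajectory
  ov <- data.frame(label = "overall", histology = NA_character_,
                   lesion_size_mm = NA_real_, length_mm = NA_real_,
                   tp = report$overall$counts$tp,
                   fp = report$overall$counts$fp,
                   tn = report$overall$counts$tn,
                   fn = report$overall$counts$fn,
                   sensitivity = report$overall$sensitivity,
                   specificity = report$overall$specificity)
  utils::write.csv(rbind(df, ov), path, row.names = FALSE)
  invisible(path)
}
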