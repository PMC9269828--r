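#' Detector tuning constants
#'
#' The outlier detector forecasts the image maximum amplitude of the next
#' frame by simple exponential smoothing and raises an alarm when the
#' observed maximum lies strictly above its forecast confidence band. The
#' band half-width is `delta` times an exponentially smoothed absolute
#' deviation.
#'
#' @param alpha Smoothing constant in `[0, 1]`; larger values track the
#'   series faster. Default 0.3.
#' @param delta Band multiplier (> 1); larger values make the detector more
#'   conservative (higher specificity, lower sensitivity). Default 3.
#' @param warmup Number of initial scored frames with alarms forced off
#'   while the level and deviation estimates settle (>= 1). Default 3.
#' @param two_sided If `TRUE`, values below the lower band also raise an
#'   alarm; the default (`FALSE`) triggers on the upper band only, since a
#'   lesion raises the image maximum.
#' @param deviation_ref Whether the deviation recursion measures
#'   `|y - level|` against the freshly `"updated"` level (default) or the
#'   `"previous"` one.
#' @return An object of class `mw_detector_config`.
#' @export
detector_config <- function(alpha = 0.3, delta = 3, warmup = 3,
                            two_sided = FALSE,
                            deviation_ref = c("updated", "previous")) {
  deviation_ref <- match.arg(deviation_ref)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (delta <= 1) stop("delta must be > 1", call. = FALSE)
  if (warmup < 1 || warmup != round(warmup)) {
    stop("warmup must be an integer >= 1", call. = FALSE)
  }
  structure(list(alpha = alpha, delta = delta, warmup = as.integer(warmup),
                 two_sided = isTRUE(two_sided),
                 deviation_ref = deviation_ref),
            class = "mw_detector_config")
}

#' Exponential-smoothing level update
#'
#' `level_next = alpha * y + (1 - alpha) * level`: `alpha = 1` copies the
#' observation, `alpha = 0` keeps the running level.
#'
#' @param level Current level estimate.
#' @param y Observed image maximum amplitude.
#' @param alpha Smoothing constant in `[0, 1]`.
#' @return The updated level.
#' @export
update_level <- function(level, y, alpha) {
  alpha * y + (1 - alpha) * level
}

#' Confidence-band update
#'
#' Updates the smoothed absolute deviation,
#' `dev_next = alpha * |y - level_ref| + (1 - alpha) * deviation`, and
#' returns the band `level_next +/- delta * dev_next`. With a constant
#' series and zero deviation the band collapses onto the level.
#'
#' @param level_next The already-updated level (see [update_level()]).
#' @param y The observation that produced `level_next`.
#' @param deviation Current smoothed absolute deviation (>= 0).
#' @param alpha,delta Detector constants.
#' @param level_prev Previous level; used instead of `level_next` in the
#'   deviation residual when `deviation_ref = "previous"`.
#' @param deviation_ref `"updated"` (default) or `"previous"`.
#' @return List with `band_low`, `band_high`, `deviation`.
#' @export
update_band <- function(level_next, y, deviation, alpha, delta,
                        level_prev = level_next,
                        deviation_ref = c("updated", "previous")) {
  deviation_ref <- match.arg(deviation_ref)
  ref <- if (deviation_ref == "updated") level_next else level_prev
  dev_next <- alpha * abs(y - ref) + (1 - alpha) * deviation
  list(band_low = level_next - delta * dev_next,
       band_high = level_next + delta * dev_next,
       deviation = dev_next)
}

new_detector_state <- function() {
  list(level = NA_real_, deviation = 0, frame_count = 0L)
}

#' Score one observation and advance the detector state
#'
#' The alarm decision compares `y` with the band forecast from the previous
#' state (`level +/- delta * deviation`), strictly: `y` exactly on the band
#' edge does not alarm. Alarms are forced off for the first `warmup` scored
#' observations; the state updates regardless. The first observation ever
#' initialises the level to `y` with zero deviation.
#'
#' @param state Detector state as returned by previous calls (or
#'   `new_detector_state()` internally); a list with `level`, `deviation`,
#'   `frame_count`.
#' @param y Observed image maximum amplitude.
#' @param config An [detector_config()].
#' @return List with `alarm` (logical), `level`, `band_low`, `band_high`
#'   (the forecast values `y` was scored against) and `state` (updated).
#' @export
score_frame <- function(state, y, config) {
  stopifnot(inherits(config, "mw_detector_config"))
  if (is.na(state$level)) {
    # first scored observation: initialise, never alarm
    fc_level <- y; fc_low <- y; fc_high <- y
    alarm <- FALSE
    state$level <- y
    state$deviation <- 0
  } else {
    fc_level <- state$level
    half <- config$delta * state$deviation
    fc_low <- fc_level - half
    fc_high <- fc_level + half
    alarm <- (y > fc_high) ||
      (config$two_sided && y < fc_low)
    if (state$frame_count < config$warmup) alarm <- FALSE
    level_prev <- state$level
    state$level <- update_level(state$level, y, config$alpha)
    band <- update_band(state$level, y, state$deviation, config$alpha,
                        config$delta, level_prev = level_prev,
                        deviation_ref = config$deviation_ref)
    state$deviation <- band$deviation
  }
  state$frame_count <- state$frame_count + 1L
  list(alarm = alarm, level = fc_level, band_low = fc_low,
       band_high = fc_high, state = state)
}

#' Score a series of image maxima
#'
#' Applies [score_frame()] along a numeric series, returning the per-step
#' forecast level, band and alarm flag.
#'
#' @param y Numeric vector of image maxima (one per scored frame, in order).
#' @param config An [detector_config()].
#' @return Data frame with columns `step`, `y`, `level`, `band_low`,
#'   `band_high`, `alarm`.
#' @export
score_series <- function(y, config = detector_config()) {
  state <- new_detector_state()
  out <- data.frame(step = seq_along(y), y = y, level = NA_real_,
                    band_low = NA_real_, band_high = NA_real_,
                    alarm = FALSE)
  for (i in seq_along(y)) {
    r <- score_frame(state, y[i], config)
    state <- r$state
    out$level[i] <- r$level
    out$band_low[i] <- r$band_low
    out$band_high[i] <- r$band_high
    out$alarm[i] <- r$alarm
  }
  out
}

#' Run the full detection pipeline on a trajectory
#'
#' For every frame after the first: select and subtract the most similar
#' previous frame (automatic temporal calibration), reconstruct the
#' cross-sectional image, take its maximum amplitude, and score it with the
#' exponential-smoothing outlier detector. Frame 0 has no possible reference
#' and is reported with `alarm = FALSE` and `y = NA`.
#'
#' @param traj An `mw_trajectory` with at least `warmup + 2` frames.
#' @param config An [detector_config()].
#' @param metric Frame-similarity metric for reference selection
#'   ([frame_distance()]).
#' @param grid Image grid for reconstruction.
#' @param field_power Passed to [reconstruct()].
#' @param pool_window Passed to [calibrate_trajectory()].
#' @return An object of class `mw_detection`: a data frame with one row per
#'   frame and columns `frame_index`, `z_mm`, `reference_index`, `y`,
#'   `level`, `band_low`, `band_high`, `alarm`, carrying the config as
#'   attribute `"config"`.
#' @export
run_detector <- function(traj, config = detector_config(),
                         metric = c("mhd", "chebyshev"),
                         grid = image_grid(), field_power = 2,
                         pool_window = Inf) {
  stopifnot(inherits(traj, "mw_trajectory"))
  metric <- match.arg(metric)
  n <- length(traj$frames)
  if (n < config$warmup + 2L) {
    stop(sprintf("trajectory too short: need at least %d frames",
                 config$warmup + 2L), call. = FALSE)
  }
  cal <- calibrate_trajectory(traj, metric = metric,
                              pool_window = pool_window)
  freq <- traj$frames[[1]]$frequency_hz
  w <- receiver_weights(traj$geometry, grid, freq)

  out <- data.frame(frame_index = 0:(n - 1L), z_mm = frame_z(traj),
                    reference_index = NA_integer_, y = NA_real_,
                    level = NA_real_, band_low = NA_real_,
                    band_high = NA_real_, alarm = FALSE)
  state <- new_detector_state()
  for (i in 2:n) {
    img <- reconstruct(cal[[i]], traj$geometry, grid, freq,
                       field_power = field_power, weights = w)
    r <- score_frame(state, img$max_amplitude, config)
    state <- r$state
    out$reference_index[i] <- cal[[i]]$reference_index
    out$y[i] <- img$max_amplitude
    out$level[i] <- r$level
    out$band_low[i] <- r$band_low
    out$band_high[i] <- r$band_high
    out$alarm[i] <- r$alarm
  }
  attr(out, "config") <- config
  class(out) <- c("mw_detection", "data.frame")
  out
}
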