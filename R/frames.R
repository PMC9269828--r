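#' One S-parameter acquisition frame
#'
#' A frame is a single acquisition step along the colon axis: the complex
#' transmission coefficients of every transmitter-receiver pair in the
#' measurement plan, measured at a single frequency, together with the frame
#' index and its axial position.
#'
#' @param frame_index Integer frame index `n >= 0`.
#' @param z_mm Axial position of the frame in mm.
#' @param values Complex vector of transmission coefficients, one per plan
#'   pair, in plan order. May carry names `"tx-rx"`; they are checked against
#'   the plan when present.
#' @param plan The `mw_plan` the values follow.
#' @param frequency_hz Acquisition frequency in Hz. Default 7.6e9.
#' @return An object of class `mw_frame`.
#' @export
sparam_frame <- function(frame_index, z_mm, values, plan, frequency_hz = 7.6e9) {
  stopifnot(inherits(plan, "mw_plan"))
  if (!is.numeric(frame_index) || length(frame_index) != 1 ||
      frame_index != round(frame_index) || frame_index < 0) {
    stop("`frame_index` must be a single integer >= 0", call. = FALSE)
  }
  if (!is.numeric(frequency_hz) || length(frequency_hz) != 1 ||
      frequency_hz <= 0) {
    stop("`frequency_hz` must be positive", call. = FALSE)
  }
  values <- as.complex(values)
  keys <- pair_keys(plan)
  if (length(values) != length(keys)) {
    stop(sprintf("frame %d: expected %d pair values, got %d",
                 frame_index, length(keys), length(values)), call. = FALSE)
  }
  if (!is.null(names(values)) && !identical(names(values), keys)) {
    stop(sprintf("frame %d: value names do not match the measurement plan",
                 frame_index), call. = FALSE)
  }
  if (any(!is.finite(Re(values)) | !is.finite(Im(values)))) {
    stop(sprintf("frame %d: non-finite S-parameter value", frame_index),
         call. = FALSE)
  }
  names(values) <- keys
  structure(
    list(frame_index = as.integer(frame_index), z_mm = as.numeric(z_mm),
         frequency_hz = as.numeric(frequency_hz), values = values,
         plan = plan),
    class = "mw_frame"
  )
}

#' @export
print.mw_frame <- function(x, ...) {
  cat(sprintf("<mw_frame> n=%d, z=%.1f mm, %d pairs @ %.3g GHz\n",
              x$frame_index, x$z_mm, length(x$values), x$frequency_hz / 1e9))
  invisible(x)
}

#' Ground-truth lesion extent
#'
#' Records the axial extent of one neoplasm along the trajectory, as
#' registered against the beginning of the trajectory, with its histology
#' label and reported size.
#'
#' @param z_start_mm,z_end_mm Axial extent in mm (`z_start_mm < z_end_mm`).
#' @param histology_label One of `"adenoma_hgd"`, `"adenocarcinoma"`,
#'   `"other"`.
#' @param size_mm Reported lesion size in mm (> 0).
#' @return An object of class `mw_lesion` (a named list).
#' @export
lesion_truth <- function(z_start_mm, z_end_mm,
                         histology_label = c("other", "adenoma_hgd",
                                             "adenocarcinoma"),
                         size_mm = z_end_mm - z_start_mm) {
  histology_label <- match.arg(histology_label)
  if (!(z_start_mm < z_end_mm)) {
    stop("lesion must have z_start_mm < z_end_mm", call. = FALSE)
  }
  if (size_mm <= 0) stop("lesion size_mm must be > 0", call. = FALSE)
  structure(list(z_start_mm = as.numeric(z_start_mm),
                 z_end_mm = as.numeric(z_end_mm),
                 histology_label = histology_label,
                 size_mm = as.numeric(size_mm)),
            class = "mw_lesion")
}

#' Ordered frame sequence along a colon trajectory
#'
#' @param frames List of [sparam_frame()] objects with consecutive
#'   `frame_index` starting at 0 and uniform z spacing `step_mm`.
#' @param step_mm Axial step between frames in mm. Default 4.
#' @param geometry The `mw_geometry` of the acquiring array.
#' @param lesions List of [lesion_truth()] ground-truth extents (may be
#'   empty).
#' @param label Free-text identifier for the trajectory.
#' @param provenance Optional named list recording how the trajectory was
#'   produced (e.g. simulator seed and parameters); stored in the metadata
#'   sidecar on write.
#' @return An object of class `mw_trajectory`.
#' @export
trajectory <- function(frames, step_mm = 4, geometry = array_geometry(),
                       lesions = list(), label = "", provenance = NULL) {
  stopifnot(inherits(geometry, "mw_geometry"))
  if (length(frames) == 0) stop("no frames", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "mw_frame"))) {
    stop("`frames` must be a list of mw_frame objects", call. = FALSE)
  }
  if (step_mm <= 0) stop("`step_mm` must be > 0", call. = FALSE)
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (!identical(idx, seq_along(frames) - 1L)) {
    stop("frame indices must be consecutive starting at 0", call. = FALSE)
  }
  z0 <- frames[[1]]$z_mm
  z <- vapply(frames, `[[`, numeric(1), "z_mm")
  if (any(abs(z - (z0 + idx * step_mm)) > 1e-9)) {
    stop("frame z positions must advance uniformly by `step_mm`",
         call. = FALSE)
  }
  freq <- vapply(frames, `[[`, numeric(1), "frequency_hz")
  if (length(unique(freq)) != 1) {
    stop("all frames must share one acquisition frequency", call. = FALSE)
  }
  keys0 <- names(frames[[1]]$values)
  for (f in frames) {
    if (!identical(names(f$values), keys0)) {
      stop("all frames must share one measurement plan", call. = FALSE)
    }
  }
  if (length(lesions) > 0 &&
      !all(vapply(lesions, inherits, logical(1), "mw_lesion"))) {
    stop("`lesions` must be a list of mw_lesion objects", call. = FALSE)
  }
  structure(
    list(frames = frames, step_mm = as.numeric(step_mm), geometry = geometry,
         plan = frames[[1]]$plan, lesions = lesions,
         label = as.character(label), provenance = provenance),
    class = "mw_trajectory"
  )
}

#' @export
print.mw_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mw_trajectory> '%s': %d frames, step %.1f mm, %d pairs, %d lesion(s)\n",
    x$label, length(x$frames), x$step_mm, nrow(x$plan), length(x$lesions)))
  invisible(x)
}

#' @export
length.mw_trajectory <- function(x) length(x$frames)

#' Frame values of a trajectory as a complex matrix
#'
#' @param traj An `mw_trajectory`.
#' @return Complex matrix, one row per frame (in order), one column per plan
#'   pair, with column names `"tx-rx"`.
#' @export
frame_matrix <- function(traj) {
  stopifnot(inherits(traj, "mw_trajectory"))
  m <- t(vapply(traj$frames, function(f) f$values,
                complex(length(traj$frames[[1]]$values))))
  rownames(m) <- NULL
  m
}

#' Axial positions of all frames
#'
#' @param traj An `mw_trajectory`.
#' @return Numeric vector of z positions in mm, one per frame.
#' @export
frame_z <- function(traj) {
  vapply(traj$frames, `[[`, numeric(1), "z_mm")
}
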