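#' Modified Hausdorff distance between two planar point sets
#'
#' `MHD(A, B) = max(d(A, B), d(B, A))` where `d(A, B)` is the mean over
#' points of `A` of the Euclidean distance to the nearest point of `B`. The
#' mean-of-minima construction is more robust to single outliers than the
#' classical Hausdorff maximum; it is symmetric and zero for identical sets
#' but does not satisfy the triangle inequality in general.
#'
#' @param a,b Numeric matrices with 2 columns (x, y), one row per point;
#'   both non-empty.
#' @return A single non-negative number.
#' @examples
#' modified_hausdorff_distance(cbind(0, 0), cbind(3, 4))  # 5
#' @export
modified_hausdorff_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("point sets must be non-empty", call. = FALSE)
  }
  if (ncol(a) != 2 || ncol(b) != 2) {
    stop("point sets must have two columns (x, y)", call. = FALSE)
  }
  # full pairwise distance matrix: |A| x |B|
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  d <- sqrt(d2)
  max(mean(apply(d, 1, min)), mean(apply(d, 2, min)))
}

frame_points <- function(values) {
  cbind(Re(values), Im(values))
}

#' Distance between two S-parameter frames
#'
#' Two readings of frame similarity are supported. `"mhd"` treats each
#' frame's transmission coefficients as a set of points in the complex plane
#' (Re, Im) and applies the modified Hausdorff distance; `"chebyshev"` is
#' the channel-wise maximum modulus of the difference. Both are symmetric,
#' non-negative and zero for identical frames.
#'
#' @param f,g `mw_frame` (or calibrated-frame) objects sharing one
#'   measurement plan and frequency.
#' @param metric `"mhd"` (default) or `"chebyshev"`.
#' @return A single non-negative number.
#' @export
frame_distance <- function(f, g, metric = c("mhd", "chebyshev")) {
  metric <- match.arg(metric)
  if (!identical(names(f$values), names(g$values))) {
    stop("frames do not share a measurement plan", call. = FALSE)
  }
  if (!is.null(f$frequency_hz) && !is.null(g$frequency_hz) &&
      f$frequency_hz != g$frequency_hz) {
    stop("frames do not share an acquisition frequency", call. = FALSE)
  }
  if (metric == "chebyshev") {
    max(Mod(f$values - g$values))
  } else {
    modified_hausdorff_distance(frame_points(f$values),
                                frame_points(g$values))
  }
}

#' Select the calibration reference for a frame
#'
#' Automatic temporal subtraction calibration picks, from the pool of
#' previously acquired frames, the one with the most similar S-parameters to
#' the current frame. Ties are broken in favour of the most recent pool
#' frame (largest index).
#'
#' @param current The `mw_frame` being calibrated.
#' @param pool List of previous `mw_frame`s (all with `frame_index` smaller
#'   than the current frame's).
#' @param metric Passed to [frame_distance()].
#' @return The selected pool frame.
#' @export
select_reference <- function(current, pool, metric = c("mhd", "chebyshev")) {
  metric <- match.arg(metric)
  if (length(pool) == 0) {
    stop("no reference available: pool of previous frames is empty",
         call. = FALSE)
  }
  idx <- vapply(pool, `[[`, integer(1), "frame_index")
  if (any(idx >= current$frame_index)) {
    stop("pool may contain only frames earlier than the current one",
         call. = FALSE)
  }
  d <- vapply(pool, frame_distance, numeric(1), f = current, metric = metric)
  best <- which(d == min(d))
  pool[[best[which.max(idx[best])]]]
}

#' Subtract a reference frame to isolate the scattered field
#'
#' The calibrated frame is the pairwise complex difference
#' `current - reference`: wall clutter and other slowly varying effects that
#' the two frames share cancel, leaving an estimate of the scattered field
#' due to a lesion.
#'
#' @param current,reference `mw_frame`s sharing one plan and frequency.
#' @return An object of class `mw_calibrated` with fields `frame_index`,
#'   `reference_index`, `values` (named complex vector), `plan`,
#'   `frequency_hz`.
#' @export
calibrate <- function(current, reference) {
  if (!identical(names(current$values), names(reference$values))) {
    stop("frames do not share a measurement plan", call. = FALSE)
  }
  if (current$frequency_hz != reference$frequency_hz) {
    stop("frames do not share an acquisition frequency", call. = FALSE)
  }
  structure(
    list(frame_index = current$frame_index,
         reference_index = reference$frame_index,
         z_mm = current$z_mm,
         values = current$values - reference$values,
         plan = current$plan,
         frequency_hz = current$frequency_hz),
    class = "mw_calibrated"
  )
}

#' @export
print.mw_calibrated <- function(x, ...) {
  cat(sprintf("<mw_calibrated> n=%d (ref %d), residual energy %.3g\n",
              x$frame_index, x$reference_index, sum(Mod(x$values)^2)))
  invisible(x)
}

#' Calibrate every frame of a trajectory
#'
#' Applies automatic temporal subtraction calibration frame by frame: for
#' each frame `n >= 1` the most similar frame among frames `0..n-1` (or the
#' most recent `pool_window` of them) is selected and subtracted. Frame 0
#' has no predecessors and is never calibrated; it is returned as `NULL` in
#' the output list.
#'
#' @param traj An `mw_trajectory`.
#' @param metric Passed to [frame_distance()].
#' @param pool_window Number of most recent previous frames eligible as
#'   references; `Inf` (default) uses all previous frames.
#' @return A list, one element per frame: `NULL` for frame 0, otherwise an
#'   `mw_calibrated`.
#' @export
calibrate_trajectory <- function(traj, metric = c("mhd", "chebyshev"),
                                 pool_window = Inf) {
  stopifnot(inherits(traj, "mw_trajectory"))
  metric <- match.arg(metric)
  n <- length(traj$frames)
  out <- vector("list", n)
  for (i in seq_len(n - 1L)) {        # frame index i, pool 0..i-1
    lo <- if (is.finite(pool_window)) max(1L, i - pool_window + 1L) else 1L
    pool <- traj$frames[lo:i]
    ref <- select_reference(traj$frames[[i + 1L]], pool, metric = metric)
    out[[i + 1L]] <- calibrate(traj$frames[[i + 1L]], ref)
  }
  out
}
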