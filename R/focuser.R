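SPEED_OF_LIGHT <- 299792458  # m/s

#' Free-space wavenumber
#'
#' `k = 2 * pi * f / c` with `c` the speed of light; the lumen is insufflated
#' with carbon dioxide during acquisition, so propagation inside it is
#' treated as free space. At 7.6 GHz, `k` is about 159.3 rad/m (wavelength
#' about 39.4 mm).
#'
#' @param frequency_hz Frequency in Hz (> 0).
#' @return Wavenumber in rad/m.
#' @export
wavenumber <- function(frequency_hz) {
  if (!is.numeric(frequency_hz) || any(frequency_hz <= 0)) {
    stop("frequency must be positive", call. = FALSE)
  }
  2 * pi * frequency_hz / SPEED_OF_LIGHT
}

#' Square pixel grid for cross-sectional images
#'
#' A square XY window centred on the array axis. The pixel count per axis is
#' forced odd so the origin is a pixel centre.
#'
#' @param extent_mm Half-width of the window in mm. Default 45, covering a
#'   90 mm colon diameter.
#' @param spacing_mm Pixel pitch in mm. Default 1.
#' @return An object of class `mw_grid` with fields `extent_mm`,
#'   `spacing_mm`, `coords_mm` (pixel centre coordinates shared by both
#'   axes) and `n` (pixels per axis, odd).
#' @export
image_grid <- function(extent_mm = 45, spacing_mm = 1) {
  if (spacing_mm <= 0) stop("spacing must be > 0", call. = FALSE)
  if (extent_mm <= 0) stop("extent must be > 0", call. = FALSE)
  half <- floor(extent_mm / spacing_mm)
  coords <- seq(-half, half) * spacing_mm
  structure(list(extent_mm = as.numeric(extent_mm),
                 spacing_mm = as.numeric(spacing_mm),
                 coords_mm = coords, n = length(coords)),
            class = "mw_grid")
}

# Per-receiver backprojection weights on a grid: for receiver at (x, y) mm,
# W(r) = J1(2 k d(r)) * exp(1i * 2 k d(r)) with d the receiver-pixel
# distance in metres. Returned as a list of n_antennas complex matrices.
receiver_weights <- function(geometry, grid, frequency_hz) {
  k <- wavenumber(frequency_hz)
  pos <- antenna_positions(geometry)
  px <- matrix(grid$coords_mm, grid$n, grid$n)        # x varies along rows
  py <- matrix(grid$coords_mm, grid$n, grid$n, byrow = TRUE)
  lapply(seq_len(geometry$n_antennas), function(j) {
    d <- sqrt((px - pos[j, 1])^2 + (py - pos[j, 2])^2) / 1000  # mm -> m
    arg <- 2 * k * d
    besselJ(arg, 1) * exp(1i * arg)
  })
}

#' Reconstruct the cross-sectional microwave image of a calibrated frame
#'
#' Monofocusing backprojection of the calibrated scattered field onto an XY
#' pixel grid. Each measured pair `(i, j)` contributes
#' `Es^2 * J1(2 k |r_Rj - r|) * exp(1i * (2 k |r_Rj - r| + phi_ij))` at pixel
#' `r`, where `Es` is the pair's calibrated value, `J1` the Bessel function
#' of the first kind of order one, `k` the free-space wavenumber (distances
#' in metres) and `phi_ij` the transmitter-receiver angular separation. The
#' stored image is the pixel-wise modulus of the complex sum; the complex
#' field is retained for diagnostics. `J1(0) = 0`, so pixels at a receiver
#' position are naturally suppressed rather than singular.
#'
#' @param cal An `mw_calibrated` (or any object with named complex `values`
#'   following the plan and a `plan` field).
#' @param geometry The `mw_geometry` of the array.
#' @param grid An [image_grid()].
#' @param frequency_hz Acquisition frequency; defaults to the frame's own.
#' @param field_power Exponent applied to the calibrated value before
#'   backprojection; 2 (default) is the monofocusing convention (complex
#'   square of the scattered field), 1 backprojects the field itself.
#' @param weights Optional precomputed [receiver_weights()] list (an
#'   optimisation for repeated reconstructions on one grid).
#' @return An object of class `mw_image` with fields `grid`, `amplitude`
#'   (non-negative matrix, x along rows), `field` (complex matrix),
#'   `frame_index` and `max_amplitude`.
#' @export
reconstruct <- function(cal, geometry, grid = image_grid(),
                        frequency_hz = cal$frequency_hz, field_power = 2,
                        weights = NULL) {
  stopifnot(inherits(geometry, "mw_geometry"), inherits(grid, "mw_grid"))
  plan <- cal$plan
  if (is.null(plan)) stop("calibrated frame carries no plan", call. = FALSE)
  if (any(plan$tx >= geometry$n_antennas | plan$rx >= geometry$n_antennas)) {
    stop("plan pair refers to an antenna outside the geometry",
         call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- receiver_weights(geometry, grid, frequency_hz)
  }
  phi <- pair_angles(plan, geometry)
  es <- cal$values^field_power
  field <- matrix(0 + 0i, grid$n, grid$n)
  for (p in seq_len(nrow(plan))) {
    field <- field + es[p] * exp(1i * phi[p]) * weights[[plan$rx[p] + 1L]]
  }
  amp <- Mod(field)
  structure(list(grid = grid, amplitude = amp, field = field,
                 frame_index = cal$frame_index,
                 max_amplitude = max(amp)),
            class = "mw_image")
}

#' @export
print.mw_image <- function(x, ...) {
  cat(sprintf("<mw_image> n=%s, %dx%d px @ %.2g mm, max %.4g\n",
              x$frame_index %||% "?", x$grid$n, x$grid$n,
              x$grid$spacing_mm, x$max_amplitude))
  invisible(x)
}

#' Pixel location of the image maximum
#'
#' @param image An `mw_image`.
#' @return Numeric `(x, y)` in mm of the first pixel attaining the maximum.
#' @export
image_argmax <- function(image) {
  ij <- which(image$amplitude == max(image$amplitude), arr.ind = TRUE)[1, ]
  c(x = image$grid$coords_mm[ij[1]], y = image$grid$coords_mm[ij[2]])
}

#' Per-pair maximum image amplitude in the sector facing each pair
#'
#' For each measured pair, reconstructs the single-pair partial image and
#' takes the maximum amplitude over the angular sector facing the pair
#' (the transmitter-receiver midpoint bearing plus/minus half the antenna
#' spacing). Values are normalised to the largest across pairs, mirroring
#' how a per-channel lesion bearing is read off the array.
#'
#' @inheritParams reconstruct
#' @return Named numeric vector (names `"tx-rx"`), maxima normalised to 1
#'   (all zeros when every partial image is zero).
#' @export
per_pair_max <- function(cal, geometry, grid = image_grid(),
                         frequency_hz = cal$frequency_hz, field_power = 2) {
  stopifnot(inherits(geometry, "mw_geometry"), inherits(grid, "mw_grid"))
  plan <- cal$plan
  weights <- receiver_weights(geometry, grid, frequency_hz)
  phi <- pair_angles(plan, geometry)
  es <- cal$values^field_power

  px <- matrix(grid$coords_mm, grid$n, grid$n)
  py <- matrix(grid$coords_mm, grid$n, grid$n, byrow = TRUE)
  pang <- atan2(py, px)
  half_sector <- pi / geometry$n_antennas

  out <- numeric(nrow(plan))
  for (p in seq_len(nrow(plan))) {
    ai <- geometry$angles_rad[plan$tx[p] + 1L]
    aj <- geometry$angles_rad[plan$rx[p] + 1L]
    # bisector of the two antenna bearings, robust to wrap-around
    mid <- atan2(sin(ai) + sin(aj), cos(ai) + cos(aj))
    dang <- abs(((pang - mid + pi) %% (2 * pi)) - pi)
    partial <- Mod(es[p] * exp(1i * phi[p]) * weights[[plan$rx[p] + 1L]])
    out[p] <- max(partial[dang <= half_sector])
  }
  names(out) <- pair_keys(plan)
  m <- max(out)
  if (m > 0) out / m else out
}
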