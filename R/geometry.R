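#' Ring antenna array geometry
#'
#' Describes the circular switchable antenna array mounted on the colonoscope
#' tip: `n_antennas` transmitting antennas (and the same number of receiving
#' antennas) evenly spaced on a ring of radius `ring_radius_mm`. Antenna `i`
#' (zero-based) sits at angle `2 * pi * i / n_antennas`, counter-clockwise,
#' with antenna 0 at angle 0. The transmitting and receiving rings are treated
#' as coplanar for cross-sectional (XY-plane) imaging; the axial offset
#' between the two physical rings is kept as a field for completeness but
#' defaults to zero.
#'
#' @param n_antennas Number of antennas per ring (>= 3). Default 8.
#' @param ring_radius_mm Ring radius in mm. Default 10 (a 20 mm diameter
#'   accessory).
#' @param tx_rx_ring_offset_z_mm Axial offset between the transmitting and
#'   receiving rings in mm. Default 0 (coplanar).
#' @return An object of class `mw_geometry` with fields `n_antennas`,
#'   `ring_radius_mm`, `angles_rad` (length `n_antennas`) and
#'   `tx_rx_ring_offset_z_mm`.
#' @examples
#' geom <- array_geometry()
#' antenna_positions(geom)
#' @export
array_geometry <- function(n_antennas = 8, ring_radius_mm = 10,
                           tx_rx_ring_offset_z_mm = 0) {
  if (!is.numeric(n_antennas) || length(n_antennas) != 1 ||
      n_antennas != round(n_antennas) || n_antennas < 3) {
    stop("`n_antennas` must be a single integer >= 3", call. = FALSE)
  }
  if (!is.numeric(ring_radius_mm) || length(ring_radius_mm) != 1 ||
      ring_radius_mm <= 0) {
    stop("`ring_radius_mm` must be a single positive number", call. = FALSE)
  }
  n <- as.integer(n_antennas)
  structure(
    list(
      n_antennas = n,
      ring_radius_mm = as.numeric(ring_radius_mm),
      angles_rad = 2 * pi * (seq_len(n) - 1L) / n,
      tx_rx_ring_offset_z_mm = as.numeric(tx_rx_ring_offset_z_mm)
    ),
    class = "mw_geometry"
  )
}

#' @export
print.mw_geometry <- function(x, ...) {
  cat(sprintf("<mw_geometry> %d antennas per ring, radius %.1f mm\n",
              x$n_antennas, x$ring_radius_mm))
  invisible(x)
}

#' Antenna positions in the array cross-section
#'
#' @param geometry An [array_geometry()] object.
#' @return A `n_antennas` x 2 numeric matrix of (x, y) positions in mm.
#' @export
antenna_positions <- function(geometry) {
  stopifnot(inherits(geometry, "mw_geometry"))
  r <- geometry$ring_radius_mm
  cbind(x = r * cos(geometry$angles_rad), y = r * sin(geometry$angles_rad))
}

#' Build the transmitter-receiver measurement plan
#'
#' For every transmitter `i` the acquisition measures the three receiving
#' antennas closest to it: the facing antenna `i` and its two neighbours
#' `(i - 1) mod N` and `(i + 1) mod N`. The plan lists pairs ordered by
#' transmitter, and within a transmitter in the order `i - 1`, `i`, `i + 1`,
#' so an 8-antenna ring yields 24 pairs (transmitter 0 pairs with receivers
#' 7, 0, 1; transmitter 7 with 6, 7, 0).
#'
#' @param geometry An [array_geometry()] object.
#' @return An object of class `mw_plan`: a data.frame with integer columns
#'   `tx` and `rx` (zero-based antenna indices), one row per measured pair.
#' @examples
#' plan <- build_measurement_plan(array_geometry())
#' nrow(plan)  # 24
#' @export
build_measurement_plan <- function(geometry) {
  stopifnot(inherits(geometry, "mw_geometry"))
  n <- geometry$n_antennas
  tx <- rep(0:(n - 1L), each = 3L)
  rx <- as.integer((tx + rep(c(-1L, 0L, 1L), times = n)) %% n)
  plan <- data.frame(tx = tx, rx = rx)
  class(plan) <- c("mw_plan", "data.frame")
  plan
}

#' Canonical pair labels for a measurement plan
#'
#' @param plan An `mw_plan`.
#' @return Character vector `"tx-rx"`, one entry per pair, in plan order.
#' @keywords internal
pair_keys <- function(plan) {
  paste0(plan$tx, "-", plan$rx)
}

#' Angular separation between transmitter and receiver of each pair
#'
#' The phase correction used by the monofocusing focuser: for a pair `(i, j)`
#' the angle is `2 * pi * ((j - i) mod N) / N`.
#'
#' @param plan An `mw_plan`.
#' @param geometry The matching `mw_geometry`.
#' @return Numeric vector of angles in radians, one per pair.
#' @export
pair_angles <- function(plan, geometry) {
  stopifnot(inherits(plan, "mw_plan"), inherits(geometry, "mw_geometry"))
  n <- geometry$n_antennas
  2 * pi * (((plan$rx - plan$tx) %% n) / n)
}

assert_same_plan <- function(a, b) {
  if (!identical(paste0(a$tx, "-", a$rx), paste0(b$tx, "-", b$rx))) {
    stop("measurement plans do not match", call. = FALSE)
  }
  invisible(TRUE)
}
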