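#' Scene specification for the synthetic colon simulator
#'
#' Describes an insufflated colon segment traversed by the antenna array:
#' lumen geometry (radius, sinusoidal fold modulation, lateral centre-line
#' drift emulating an angulation), localized scatterers (polyps and optional
#' debris from suboptimal cleaning), the two-tissue dielectric contrast, and
#' additive complex measurement noise. Together with a seed it fully
#' determines a simulated trajectory.
#'
#' The forward model is Born single scattering with a 2D cylindrical-spread
#' kernel, matching the 2D slice assumption of the focuser; the lumen
#' interior is treated as free space (CO2 insufflation). Wall clutter is a
#' deterministic specular-like term per pair with round-trip phase over the
#' antenna-wall distance at the pair's midpoint bearing, so it varies
#' smoothly along the trajectory (the premise that clutter drifts slowly
#' while a polyp response appears abruptly). Noise and clutter levels have
#' no measured counterpart and are stand-in defaults; `noise_sigma` is set
#' so the frame-to-frame variation of the polyp-free image maximum stays
#' well below a 30 mm polyp's peak.
#'
#' @param length_mm Trajectory length in mm. Default 200.
#' @param lumen_radius_mm Lumen radius: a single number (default 25) or a
#'   function of z (mm) returning the radius in mm.
#' @param fold_amplitude_mm,fold_period_mm Sinusoidal modulation of the
#'   lumen radius along z (haustral folds). Defaults 0 and 60.
#' @param curve_amplitude_mm,curve_period_mm,curve_angle_rad Lateral drift
#'   of the lumen centre line relative to the array axis:
#'   `offset(z) = curve_amplitude_mm * sin(2 * pi * z / curve_period_mm)`
#'   applied along bearing `curve_angle_rad`. Default amplitude 0 (straight).
#' @param polyps Data frame of polyp scatterers with columns `z_center_mm`,
#'   `size_mm`, and optionally `angle_rad` (default 0), `radial_offset_mm`
#'   (default: near the wall, clamped inside the lumen) and `histology`
#'   (default `"other"`). `NULL` for none.
#' @param debris Data frame of weak debris scatterers with columns `z_mm`,
#'   `angle_rad`, and optionally `radial_offset_mm`, `strength`
#'   (dimensionless amplitude, default 0.05) and `size_mm` (axial extent,
#'   default 6). `NULL` for none.
#' @param lesion_props,background_props `mw_dielectric` for neoplasm and
#'   healthy mucosa; their contrast sets the polyp scattering amplitude.
#' @param clutter_amplitude Dimensionless wall-clutter scale. Default 1.
#' @param noise_sigma Standard deviation of the additive circular complex
#'   noise per S-parameter. Default 3 (a few percent of the wall-clutter
#'   magnitude), set so the polyp-free image-maximum variation stays well
#'   below a 30 mm polyp's peak.
#' @param seed Integer seed making the simulation reproducible.
#' @return An object of class `mw_scene`.
#' @seealso [simulate_trajectory()]
#' @export
scene_spec <- function(length_mm = 200, lumen_radius_mm = 25,
                       fold_amplitude_mm = 0, fold_period_mm = 60,
                       curve_amplitude_mm = 0, curve_period_mm = 400,
                       curve_angle_rad = 0,
                       polyps = NULL, debris = NULL,
                       lesion_props = neoplasm_props(),
                       background_props = healthy_mucosa_props(),
                       clutter_amplitude = 1, noise_sigma = 3,
                       seed = 1) {
  if (length_mm <= 0) stop("length_mm must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (fold_amplitude_mm < 0 || curve_amplitude_mm < 0) {
    stop("modulation amplitudes must be >= 0", call. = FALSE)
  }
  radius_fn <- if (is.function(lumen_radius_mm)) {
    lumen_radius_mm
  } else {
    force(lumen_radius_mm)
    function(z) rep_len(lumen_radius_mm, length(z))
  }
  if (!is.null(polyps)) {
    polyps <- as.data.frame(polyps)
    stopifnot(all(c("z_center_mm", "size_mm") %in% names(polyps)))
    if (is.null(polyps$angle_rad)) polyps$angle_rad <- 0
    if (is.null(polyps$histology)) polyps$histology <- "other"
    if (any(polyps$z_center_mm < 0 | polyps$z_center_mm > length_mm)) {
      stop("polyp z centers must lie within [0, length_mm]", call. = FALSE)
    }
    if (any(polyps$size_mm <= 0)) stop("polyp sizes must be > 0",
                                       call. = FALSE)
  }
  if (!is.null(debris)) {
    debris <- as.data.frame(debris)
    stopifnot(all(c("z_mm", "angle_rad") %in% names(debris)))
    if (is.null(debris$strength)) debris$strength <- 0.05
    if (is.null(debris$size_mm)) debris$size_mm <- 6
  }
  structure(
    list(length_mm = as.numeric(length_mm), radius_fn = radius_fn,
         fold_amplitude_mm = fold_amplitude_mm,
         fold_period_mm = fold_period_mm,
         curve_amplitude_mm = curve_amplitude_mm,
         curve_period_mm = curve_period_mm,
         curve_angle_rad = curve_angle_rad,
         polyps = polyps, debris = debris,
         lesion_props = lesion_props, background_props = background_props,
         clutter_amplitude = clutter_amplitude,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "mw_scene"
  )
}

#' @export
print.mw_scene <- function(x, ...) {
  cat(sprintf(
    "<mw_scene> %.0f mm, %d polyp(s), %d debris, curve %.1f mm, noise %.3g\n",
    x$length_mm, NROW(x$polyps), NROW(x$debris), x$curve_amplitude_mm,
    x$noise_sigma))
  invisible(x)
}

# Effective antenna-to-wall distance (mm) at bearing theta and position z:
# lumen radius with fold modulation, shifted by the centre-line drift
# component along theta, minus the antenna ring radius.
wall_distance_mm <- function(spec, geometry, theta, z) {
  r <- spec$radius_fn(z) +
    spec$fold_amplitude_mm * sin(2 * pi * z / spec$fold_period_mm)
  drift <- spec$curve_amplitude_mm * sin(2 * pi * z / spec$curve_period_mm)
  w <- r - drift * cos(theta - spec$curve_angle_rad) - geometry$ring_radius_mm
  if (any(w <= 0)) {
    stop("lumen wall intersects the antenna ring; enlarge the lumen or ",
         "reduce fold/curve amplitudes", call. = FALSE)
  }
  w
}

# 2D cylindrical-spread propagation kernel, distance d in metres
green2d <- function(d, k) exp(-1i * k * d) / sqrt(d)

# Scatterer rows in a uniform internal layout:
# x/y position (mm), complex amplitude, axial centre and decay scale (mm)
scene_scatterers <- function(spec, frequency_hz) {
  rows <- list()
  if (!is.null(spec$polyps) && nrow(spec$polyps) > 0) {
    tau <- scattering_amplitude(spec$lesion_props, spec$background_props,
                                frequency_hz)
    for (p in seq_len(nrow(spec$polyps))) {
      pol <- spec$polyps[p, ]
      r0 <- spec$radius_fn(pol$z_center_mm)
      off <- if (!is.null(spec$polyps$radial_offset_mm) &&
                 !is.na(pol$radial_offset_mm %||% NA)) {
        pol$radial_offset_mm
      } else {
        # protruding from the wall towards the lumen, kept off the ring
        min(max(r0 - pol$size_mm / 2, 13), r0 - 2)
      }
      rows[[length(rows) + 1L]] <- list(
        x = off * cos(pol$angle_rad), y = off * sin(pol$angle_rad),
        amplitude = tau * pol$size_mm / 10,
        z_center = pol$z_center_mm, z_scale = pol$size_mm / 2)
    }
  }
  if (!is.null(spec$debris) && nrow(spec$debris) > 0) {
    for (p in seq_len(nrow(spec$debris))) {
      d <- spec$debris[p, ]
      r0 <- spec$radius_fn(d$z_mm)
      off <- if (!is.null(spec$debris$radial_offset_mm) &&
                 !is.na(d$radial_offset_mm %||% NA)) {
        d$radial_offset_mm
      } else {
        r0 - 2
      }
      rows[[length(rows) + 1L]] <- list(
        x = off * cos(d$angle_rad), y = off * sin(d$angle_rad),
        amplitude = complex(real = d$strength),
        z_center = d$z_mm, z_scale = d$size_mm / 2)
    }
  }
  rows
}

#' Simulate one S-parameter frame
#'
#' Evaluates the Born single-scattering forward model at one axial position:
#' each pair value is wall clutter plus the coherent sum over scatterers of
#' `amplitude * g(d_T) * g(d_R)` with `g(d) = exp(-1i k d) / sqrt(d)` and an
#' axial Gaussian weight decaying over the scatterer size, plus i.i.d.
#' circular complex noise drawn from the current RNG state.
#'
#' @param spec An [scene_spec()].
#' @param geometry An [array_geometry()].
#' @param plan The matching [build_measurement_plan()] output.
#' @param z_mm Frame position, within `[0, length_mm]`.
#' @param frequency_hz Acquisition frequency. Default 7.6e9.
#' @return An `mw_frame` with `frame_index = 0` (reindexed by
#'   [simulate_trajectory()]).
#' @export
simulate_frame <- function(spec, geometry, plan, z_mm,
                           frequency_hz = 7.6e9) {
  stopifnot(inherits(spec, "mw_scene"))
  if (z_mm < 0 || z_mm > spec$length_mm) {
    stop("z_mm outside the scene", call. = FALSE)
  }
  k <- wavenumber(frequency_hz)
  pos <- antenna_positions(geometry)
  ai <- geometry$angles_rad[plan$tx + 1L]
  aj <- geometry$angles_rad[plan$rx + 1L]
  mid <- atan2(sin(ai) + sin(aj), cos(ai) + cos(aj))

  wall_m <- wall_distance_mm(spec, geometry, mid, z_mm) / 1000
  values <- spec$clutter_amplitude * exp(-1i * 2 * k * wall_m) / wall_m

  for (s in scene_scatterers(spec, frequency_hz)) {
    # super-Gaussian axial profile: near-flat over the lesion, steep edges
    w_ax <- exp(-((z_mm - s$z_center) / s$z_scale)^4)
    dt <- sqrt((pos[plan$tx + 1L, 1] - s$x)^2 +
               (pos[plan$tx + 1L, 2] - s$y)^2) / 1000
    dr <- sqrt((pos[plan$rx + 1L, 1] - s$x)^2 +
               (pos[plan$rx + 1L, 2] - s$y)^2) / 1000
    values <- values + s$amplitude * w_ax * green2d(dt, k) * green2d(dr, k)
  }
  if (spec$noise_sigma > 0) {
    n <- nrow(plan)
    values <- values + spec$noise_sigma / sqrt(2) *
      complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  }
  sparam_frame(0L, z_mm, values, plan, frequency_hz)
}

#' Simulate a full trajectory
#'
#' Generates frames at `z = 0, step_mm, ..., <= length_mm`, records the
#' ground-truth extent of every polyp as
#' `[z_center - size/2, z_center + size/2]`, and stores the seed and scene
#' parameters as provenance. The result is a pure function of
#' `(spec, geometry, step_mm)`: the caller's RNG state is saved and
#' restored, and the spec seed alone drives the noise.
#'
#' @inheritParams simulate_frame
#' @param step_mm Axial step in mm. Default 4.
#' @param label Trajectory label; defaults to `"sim-<seed>"`.
#' @return An `mw_trajectory` with lesion ground truth.
#' @export
simulate_trajectory <- function(spec, geometry = array_geometry(),
                                plan = build_measurement_plan(geometry),
                                step_mm = 4, frequency_hz = 7.6e9,
                                label = NULL) {
  stopifnot(inherits(spec, "mw_scene"))
  if (step_mm <= 0) stop("step_mm must be > 0", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  z <- seq(0, spec$length_mm, by = step_mm)
  frames <- vector("list", length(z))
  for (i in seq_along(z)) {
    f <- simulate_frame(spec, geometry, plan, z[i], frequency_hz)
    f$frame_index <- i - 1L
    frames[[i]] <- f
  }
  lesions <- list()
  if (!is.null(spec$polyps) && nrow(spec$polyps) > 0) {
    lesions <- lapply(seq_len(nrow(spec$polyps)), function(p) {
      pol <- spec$polyps[p, ]
      lesion_truth(pol$z_center_mm - pol$size_mm / 2,
                   pol$z_center_mm + pol$size_mm / 2,
                   histology_label = pol$histology, size_mm = pol$size_mm)
    })
  }
  trajectory(
    frames, step_mm = step_mm, geometry = geometry, lesions = lesions,
    label = label %||% paste0("sim-", spec$seed),
    provenance = list(
      simulator = "colowave Born single-scattering",
      seed = spec$seed,
      length_mm = spec$length_mm,
      curve_amplitude_mm = spec$curve_amplitude_mm,
      fold_amplitude_mm = spec$fold_amplitude_mm,
      noise_sigma = spec$noise_sigma,
      n_polyps = NROW(spec$polyps), n_debris = NROW(spec$debris)))
}
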