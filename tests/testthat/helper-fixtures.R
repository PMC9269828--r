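# Shared fixtures and independent oracles for the test suite.

default_geom <- array_geometry()
default_plan <- build_measurement_plan(default_geom)

# Independent brute-force oracle for the modified Hausdorff distance:
# plain double loop, no shared code with the implementation.
mhd_oracle <- function(a, b) {
  dir_mean <- function(p, q) {
    mins <- numeric(nrow(p))
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt((p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2)
        if (d < best) best <- d
      }
      mins[i] <- best
    }
    mean(mins)
  }
  max(dir_mean(a, b), dir_mean(b, a))
}

# A frame with given complex values on the default 24-pair plan.
make_frame <- function(values, index = 0L, z = index * 4) {
  sparam_frame(index, z, values, default_plan)
}

random_frame <- function(index = 0L) {
  n <- nrow(default_plan)
  make_frame(complex(real = rnorm(n), imaginary = rnorm(n)), index)
}

# A tiny deterministic trajectory (identical clutter-only frames + noise
# optionally), cheap enough for I/O and structure tests.
make_trajectory <- function(n_frames = 5, noise_sigma = 0, seed = 42,
                            lesions = list(), label = "fixture") {
  spec <- scene_spec(length_mm = (n_frames - 1) * 4,
                     noise_sigma = noise_sigma, seed = seed)
  traj <- simulate_trajectory(spec, label = label)
  if (length(lesions) > 0) traj$lesions <- lesions
  traj
}

# Calibrated single-scatterer frame: polyp at polar (radius_mm, angle_rad),
# noiseless, calibrated against a frame far from the polyp so the residual
# is essentially the pure scatterer response.
scatterer_cal <- function(radius_mm, angle_rad, size_mm = 20, seed = 1) {
  spec <- scene_spec(
    length_mm = 80,
    polyps = data.frame(z_center_mm = 40, size_mm = size_mm,
                        angle_rad = angle_rad, radial_offset_mm = radius_mm),
    noise_sigma = 0, seed = seed)
  f1 <- simulate_frame(spec, default_geom, default_plan, 40)
  f1$frame_index <- 1L
  f0 <- simulate_frame(spec, default_geom, default_plan, 0)
  calibrate(f1, f0)
}

calibrated_energy <- function(cal) {
  if (is.null(cal)) return(NA_real_)
  sum(Mod(cal$values)^2)
}

# Cache for the bundled 15-trajectory evaluation (shared by the synthetic
# end-to-end sensitivity and specificity checks).
.ensemble_cache <- new.env(parent = emptyenv())

ensemble_report <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.ensemble_cache[[key]])) {
    trajs <- simulate_ensemble(seed = seed)
    .ensemble_cache[[key]] <- evaluate_ensemble(trajs)
  }
  .ensemble_cache[[key]]
}
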