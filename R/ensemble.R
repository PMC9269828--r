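#' Scene specifications for the bundled evaluation ensemble
#'
#' Builds the 15 synthetic colon scenes used to benchmark the detection
#' pipeline. Their characteristics mirror the published ex vivo colon
#' examinations the method was validated on: sample lengths between 80 and
#' 330 mm, one neoplasm per trajectory with sizes between 10 and 65 mm
#' (adenomas with high-grade dysplasia in cases 1, 4 and 9, adenocarcinomas
#' otherwise), three curved trajectories emulating a colon angulation
#' (cases 11, 13 and 14) and one trajectory with debris from suboptimal
#' cleaning (case 12). Everything except the noise realisation is
#' deterministic; per-scene seeds are derived from `seed`.
#'
#' Each polyp is centred at 60% of the trajectory length, clamped so that
#' its extent stays inside the sample and leaves room for detector warm-up,
#' with a bearing that rotates around the ring across cases.
#'
#' @param seed Base integer seed; scene `k` uses `seed * 100 + k`.
#' @param lengths_mm,sizes_mm Sample lengths and lesion sizes per case.
#' @param curved_cases,debris_cases Case numbers (1-based) receiving a
#'   curved centre line or debris.
#' @return List of 15 [scene_spec()] objects, labelled `"case-1"` ...
#'   `"case-15"` via the attribute `"labels"`.
#' @export
ensemble_scenes <- function(seed = 1,
                            lengths_mm = c(200, 220, 80, 155, 190, 190, 330,
                                           320, 270, 285, 260, 180, 160,
                                           228, 97),
                            sizes_mm = c(10, 50, 36, 32, 48, 37, 65, 15, 23,
                                         34, 32, 35, 40, 37, 63),
                            curved_cases = c(11, 13, 14),
                            debris_cases = 12) {
  stopifnot(length(lengths_mm) == length(sizes_mm))
  n <- length(lengths_mm)
  hgd <- c(1, 4, 9)
  scenes <- vector("list", n)
  for (k in seq_len(n)) {
    len <- lengths_mm[k]; size <- sizes_mm[k]
    zc <- min(max(0.6 * len, size / 2 + 20), len - size / 2 - 8)
    polyp <- data.frame(
      z_center_mm = zc, size_mm = size,
      angle_rad = 2 * pi * (k - 1) / n,
      histology = if (k %in% hgd) "adenoma_hgd" else "adenocarcinoma")
    debris <- NULL
    if (k %in% debris_cases) {
      debris <- data.frame(
        z_mm = c(0.2, 0.45, 0.85) * len,
        angle_rad = c(0.5, 2.5, 4.5),
        strength = 0.05, size_mm = 6)
    }
    curve_amp <- if (k %in% curved_cases) 3 else 0
    scenes[[k]] <- scene_spec(
      length_mm = len,
      polyps = polyp, debris = debris,
      curve_amplitude_mm = curve_amp,
      curve_period_mm = 2 * len,
      curve_angle_rad = pi / 3,
      seed = seed * 100 + k)
  }
  attr(scenes, "labels") <- paste0("case-", seq_len(n))
  scenes
}

#' Simulate the bundled evaluation ensemble
#'
#' @inheritParams ensemble_scenes
#' @param step_mm Axial step in mm. Default 4.
#' @param ... Passed to [ensemble_scenes()].
#' @return List of `mw_trajectory` objects.
#' @export
simulate_ensemble <- function(seed = 1, step_mm = 4, ...) {
  scenes <- ensemble_scenes(seed = seed, ...)
  labels <- attr(scenes, "labels")
  lapply(seq_along(scenes), function(k) {
    simulate_trajectory(scenes[[k]], step_mm = step_mm, label = labels[k])
  })
}
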