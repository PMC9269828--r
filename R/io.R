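#' Trajectory file format
#'
#' A trajectory is stored as two files: a frame CSV and a JSON metadata
#' sidecar next to it.
#'
#' The CSV has the header `frame_index,z_mm,tx,rx,frequency_hz,re,im` and one
#' row per (frame, pair), with frames in index order and pairs in measurement
#' plan order. Complex values are split into real/imaginary columns; numbers
#' are written with 17 significant digits so that doubles round-trip exactly.
#' The file is UTF-8 with '.' decimal separators and LF line endings.
#'
#' The sidecar (same path with extension `.json`) records the array geometry,
#' the axial step, the trajectory label, ground-truth lesion extents and,
#' when the trajectory was simulated, the simulator seed and parameters.
#'
#' @name trajectory-format
NULL

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

fmt_num <- function(x) {
  # %.17g round-trips IEEE doubles exactly and is locale-independent here
  sprintf("%.17g", x)
}

#' Write a trajectory to disk
#'
#' Writes the frame CSV and its JSON metadata sidecar (see
#' [trajectory-format]). Output is deterministic: the same trajectory always
#' produces byte-identical files.
#'
#' @param traj An `mw_trajectory`.
#' @param path Path of the frame CSV; the sidecar is written next to it with
#'   a `.json` extension.
#' @return `path`, invisibly.
#' @seealso [read_trajectory()]
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mw_trajectory"))
  plan <- traj$plan
  n_pairs <- nrow(plan)
  lines <- character(1L + length(traj$frames) * n_pairs)
  lines[1] <- "frame_index,z_mm,tx,rx,frequency_hz,re,im"
  at <- 2L
  for (f in traj$frames) {
    lines[at:(at + n_pairs - 1L)] <- paste(
      f$frame_index, fmt_num(f$z_mm), plan$tx, plan$rx,
      fmt_num(f$frequency_hz), fmt_num(Re(f$values)), fmt_num(Im(f$values)),
      sep = ",")
    at <- at + n_pairs
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)

  meta <- list(
    geometry = list(
      n_antennas_per_ring = traj$geometry$n_antennas,
      ring_radius_mm = traj$geometry$ring_radius_mm,
      tx_rx_ring_offset_z_mm = traj$geometry$tx_rx_ring_offset_z_mm
    ),
    step_mm = traj$step_mm,
    label = traj$label,
    lesions = lapply(traj$lesions, function(l) {
      list(z_start_mm = l$z_start_mm, z_end_mm = l$z_end_mm,
           histology_label = l$histology_label, size_mm = l$size_mm)
    })
  )
  if (!is.null(traj$provenance)) meta$provenance <- traj$provenance
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  conj <- file(sidecar_path(path), open = "wb")
  on.exit(close(conj), add = TRUE)
  writeLines(json, conj, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Reads the frame CSV and JSON sidecar written by [write_trajectory()] and
#' validates the result: every frame must contain exactly the pairs of the
#' measurement plan, frame indices must be consecutive from 0, and all frames
#' must share one frequency.
#'
#' @param path Path of the frame CSV (sidecar expected next to it).
#' @return An `mw_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, colClasses = c(
    frame_index = "integer", z_mm = "numeric", tx = "integer",
    rx = "integer", frequency_hz = "numeric", re = "numeric",
    im = "numeric"))
  if (nrow(tab) == 0) stop("no frames", call. = FALSE)

  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("metadata sidecar not found: ", sc, call. = FALSE)
  meta <- jsonlite::fromJSON(sc, simplifyDataFrame = FALSE,
                             simplifyVector = TRUE)
  geom <- array_geometry(
    n_antennas = meta$geometry$n_antennas_per_ring,
    ring_radius_mm = meta$geometry$ring_radius_mm,
    tx_rx_ring_offset_z_mm = meta$geometry$tx_rx_ring_offset_z_mm %||% 0)
  plan <- build_measurement_plan(geom)
  keys <- pair_keys(plan)

  idx <- sort(unique(tab$frame_index))
  if (!identical(as.integer(idx), seq_along(idx) - 1L)) {
    stop("non-consecutive frame indices in ", path, call. = FALSE)
  }
  freq <- unique(tab$frequency_hz)
  if (length(freq) != 1) {
    stop("inconsistent frequency across frames in ", path, call. = FALSE)
  }

  frames <- vector("list", length(idx))
  for (n in idx) {
    rows <- tab[tab$frame_index == n, , drop = FALSE]
    got <- paste0(rows$tx, "-", rows$rx)
    missing <- setdiff(keys, got)
    if (length(missing) > 0) {
      stop(sprintf("frame %d: missing pair (%s)", n,
                   gsub("-", ",", missing[1])), call. = FALSE)
    }
    extra <- setdiff(got, keys)
    if (length(extra) > 0 || nrow(rows) != length(keys)) {
      stop(sprintf("frame %d: unexpected pairs for the %d-antenna plan",
                   n, geom$n_antennas), call. = FALSE)
    }
    ord <- match(keys, got)
    z <- unique(rows$z_mm)
    if (length(z) != 1) {
      stop(sprintf("frame %d: inconsistent z_mm", n), call. = FALSE)
    }
    frames[[n + 1L]] <- sparam_frame(
      frame_index = n, z_mm = z,
      values = complex(real = rows$re[ord], imaginary = rows$im[ord]),
      plan = plan, frequency_hz = freq)
  }

  lesions <- lapply(meta$lesions, function(l) {
    lesion_truth(l$z_start_mm, l$z_end_mm, l$histology_label, l$size_mm)
  })
  trajectory(frames, step_mm = meta$step_mm, geometry = geom,
             lesions = lesions, label = meta$label %||% "",
             provenance = meta$provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
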