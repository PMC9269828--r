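#' Build a scene specification from a plain list
#'
#' Converts a named list — typically parsed from a YAML scene file — into a
#' [scene_spec()]. Recognised top-level keys mirror the `scene_spec()`
#' arguments (`length_mm`, `lumen_radius_mm`, `fold_amplitude_mm`,
#' `fold_period_mm`, `curve_amplitude_mm`, `curve_period_mm`,
#' `curve_angle_rad`, `clutter_amplitude`, `noise_sigma`, `seed`), with
#' `polyps` and `debris` given as lists of per-scatterer records and the
#' tissue properties as `lesion`/`background` records with
#' `relative_permittivity` and `conductivity_s_m`.
#'
#' @param x Named list.
#' @param seed Optional seed overriding the one in `x`.
#' @return An `mw_scene`.
#' @seealso [read_scene()] for the annotated on-disk format.
#' @export
scene_from_list <- function(x, seed = NULL) {
  stopifnot(is.list(x))
  rows <- function(entries) {
    if (is.null(entries) || length(entries) == 0) return(NULL)
    do.call(rbind, lapply(entries, function(e) as.data.frame(e)))
  }
  tissue <- function(rec, default, type) {
    if (is.null(rec)) return(default)
    dielectric_props(rec$relative_permittivity, rec$conductivity_s_m, type)
  }
  args <- x[intersect(names(x),
                      c("length_mm", "lumen_radius_mm", "fold_amplitude_mm",
                        "fold_period_mm", "curve_amplitude_mm",
                        "curve_period_mm", "curve_angle_rad",
                        "clutter_amplitude", "noise_sigma", "seed"))]
  args$polyps <- rows(x$polyps)
  args$debris <- rows(x$debris)
  args$lesion_props <- tissue(x$lesion, neoplasm_props(), "neoplasm")
  args$background_props <- tissue(x$background, healthy_mucosa_props(),
                                  "healthy_mucosa")
  if (!is.null(seed)) args$seed <- seed
  do.call(scene_spec, args)
}

#' Read a scene specification from a YAML file
#'
#' @param path Path to a YAML scene file; see
#'   `system.file("extdata", "example_scene.yaml", package = "colowave")`
#'   for an annotated example.
#' @param seed Optional seed overriding the one in the file.
#' @return An `mw_scene`.
#' @export
read_scene <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML scene files requires the 'yaml' package",
         call. = FALSE)
  }
  scene_from_list(yaml::read_yaml(path), seed = seed)
}
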