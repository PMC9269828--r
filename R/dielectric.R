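#' Dielectric properties of a tissue
#'
#' Relative permittivity and conductivity of colon tissue at the acquisition
#' frequency. Neoplastic tissue shows elevated values relative to healthy
#' mucosa; at microwave frequencies near 7.6 GHz the contrast is around 30%
#' in relative permittivity and 90% in conductivity, which is the contrast
#' mechanism the imaging method exploits.
#'
#' @param relative_permittivity Dimensionless relative permittivity (>= 1).
#' @param conductivity_s_m Conductivity in S/m (>= 0).
#' @param tissue One of `"healthy_mucosa"`, `"neoplasm"`.
#' @return An object of class `mw_dielectric`.
#' @examples
#' healthy <- dielectric_props(50, 7, "healthy_mucosa")
#' lesion  <- dielectric_props(50 * 1.3, 7 * 1.9, "neoplasm")
#' Mod(scattering_amplitude(lesion, healthy))
#' @export
dielectric_props <- function(relative_permittivity, conductivity_s_m,
                             tissue = c("healthy_mucosa", "neoplasm")) {
  tissue <- match.arg(tissue)
  if (relative_permittivity < 1) {
    stop("relative_permittivity must be >= 1", call. = FALSE)
  }
  if (conductivity_s_m < 0) stop("conductivity must be >= 0", call. = FALSE)
  structure(list(relative_permittivity = as.numeric(relative_permittivity),
                 conductivity_s_m = as.numeric(conductivity_s_m),
                 tissue = tissue),
            class = "mw_dielectric")
}

EPSILON0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Complex permittivity at a frequency
#'
#' `eps* = eps_r - 1i * sigma / (2 * pi * f * eps0)` (engineering sign
#' convention).
#'
#' @param props An `mw_dielectric`.
#' @param frequency_hz Frequency in Hz.
#' @return A single complex number.
#' @export
complex_permittivity <- function(props, frequency_hz = 7.6e9) {
  stopifnot(inherits(props, "mw_dielectric"))
  if (frequency_hz <= 0) stop("frequency must be positive", call. = FALSE)
  complex(real = props$relative_permittivity,
          imaginary = -props$conductivity_s_m /
            (2 * pi * frequency_hz * EPSILON0))
}

#' Dielectric contrast between lesion and background tissue
#'
#' The complex contrast driving the Born scattering model:
#' `tau = (eps*_lesion - eps*_background) / eps*_background`. It is zero for
#' identical tissues and invariant under a common real scaling of both
#' complex permittivities.
#'
#' @param props_lesion,props_background `mw_dielectric` objects.
#' @param frequency_hz Frequency in Hz. Default 7.6e9.
#' @return A single complex contrast value.
#' @export
scattering_amplitude <- function(props_lesion, props_background,
                                 frequency_hz = 7.6e9) {
  el <- complex_permittivity(props_lesion, frequency_hz)
  eb <- complex_permittivity(props_background, frequency_hz)
  (el - eb) / eb
}

#' Default tissue properties at 7.6 GHz
#'
#' Convenience constructors for the two-tissue simulator: healthy colon
#' mucosa, and a neoplasm with 30% elevated relative permittivity and 90%
#' elevated conductivity relative to it.
#'
#' @param permittivity_contrast,conductivity_contrast Fractional elevation of
#'   the neoplasm over healthy mucosa.
#' @return An `mw_dielectric`.
#' @rdname default-tissues
#' @export
healthy_mucosa_props <- function() {
  dielectric_props(50, 7, "healthy_mucosa")
}

#' @rdname default-tissues
#' @export
neoplasm_props <- function(permittivity_contrast = 0.30,
                           conductivity_contrast = 0.90) {
  h <- healthy_mucosa_props()
  dielectric_props(h$relative_permittivity * (1 + permittivity_contrast),
                   h$conductivity_s_m * (1 + conductivity_contrast),
                   "neoplasm")
}
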