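#' Optical configuration of the speckle recording geometry
#'
#' Bundles the laser/geometry parameters of an objective-speckle bench (a
#' He-Ne laser illuminating the tissue and a bare camera in the far field)
#' together with the empirical knobs of the simulator. Defaults mirror a
#' typical bench: 632 nm He-Ne laser, 4 mm illuminated spot, camera 50 cm
#' from the sample, ~15 degree incidence.
#'
#' @param wavelength Laser wavelength in nanometres.
#' @param propagation_distance Surface-to-camera distance L in centimetres.
#' @param spot_diameter Illuminated spot diameter D in millimetres.
#' @param incidence_angle Angle between the beam and the surface normal, in
#'   degrees, in `[0, 90)`.
#' @param focal_length Imaging-lens focal length f in millimetres (only used
#'   by [subjective_speckle_size()]).
#' @param magnification Imaging magnification M (dimensionless, >= 0).
#' @param lens_diameter Imaging-lens aperture d in millimetres.
#' @param attenuation_scale Roughness scale R0 (nm) of the empirical
#'   amplitude attenuation `exp(-Ra/R0)`: rougher surfaces return less light
#'   into the collection aperture, so images darken with Ra.
#' @param patch_growth_scale Roughness scale R1 (nm) controlling the growth
#'   of the apparent bright-patch size with Ra (the coherently contributing
#'   spot shrinks as `D / (1 + Ra/R1)`, enlarging the far-field grain).
#' @param quantization_percentile,quantization_gray Quantization anchor: the
#'   given intensity percentile of the reference image of a batch is mapped
#'   to this gray level; the same scale is reused for the whole batch so
#'   absolute gray levels remain comparable across images.
#' @param diffuse_phase If `TRUE` (default) a fully developed diffuse phase
#'   screen is added to the surface phase, emulating the volume backscatter
#'   of biological tissue which randomizes the optical path even when the
#'   surface itself is optically smooth. Set `FALSE` for a bare
#'   surface-reflection model (useful for optics sanity checks).
#'
#' @return An object of class `optics_config`.
#' @export
#' @examples
#' cfg <- optics_config()
#' objective_speckle_size(cfg)
optics_config <- function(wavelength = 632,
                          propagation_distance = 50,
                          spot_diameter = 4,
                          incidence_angle = 15,
                          focal_length = 50,
                          magnification = 1,
                          lens_diameter = 10,
                          attenuation_scale = 2000,
                          patch_growth_scale = 1500,
                          quantization_percentile = 0.99,
                          quantization_gray = 250,
                          diffuse_phase = TRUE) {
  for (nm in c("wavelength", "propagation_distance", "spot_diameter",
               "focal_length", "lens_diameter", "attenuation_scale",
               "patch_growth_scale")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number.", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(incidence_angle) || incidence_angle < 0 ||
      incidence_angle >= 90) {
    stop("`incidence_angle` must lie in [0, 90) degrees.", call. = FALSE)
  }
  if (!is.numeric(magnification) || magnification < 0) {
    stop("`magnification` must be >= 0.", call. = FALSE)
  }
  if (quantization_percentile <= 0 || quantization_percentile > 1) {
    stop("`quantization_percentile` must lie in (0, 1].", call. = FALSE)
  }
  if (quantization_gray < 1 || quantization_gray > 255) {
    stop("`quantization_gray` must lie in [1, 255].", call. = FALSE)
  }
  structure(
    list(
      wavelength = wavelength,
      propagation_distance = propagation_distance,
      spot_diameter = spot_diameter,
      incidence_angle = incidence_angle,
      focal_length = focal_length,
      magnification = magnification,
      lens_diameter = lens_diameter,
      attenuation_scale = attenuation_scale,
      patch_growth_scale = patch_growth_scale,
      quantization_percentile = quantization_percentile,
      quantization_gray = quantization_gray,
      diffuse_phase = isTRUE(diffuse_phase)
    ),
    class = "optics_config"
  )
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>", x$wavelength, "nm laser, spot", x$spot_diameter,
      "mm, L =", x$propagation_distance, "cm, incidence",
      x$incidence_angle, "deg\n")
  invisible(x)
}

#' Average grain size of objective (free-space) speckle
#'
#' \deqn{\delta_O = 1.22 \lambda L / D}
#' where \eqn{\lambda} is the wavelength, L the surface-to-observation
#' distance and D the illuminated-spot diameter. A wider spot gives finer
#' speckle.
#'
#' @param cfg An [optics_config()].
#' @return Speckle grain size in micrometres.
#' @export
objective_speckle_size <- function(cfg) {
  stopifnot(inherits(cfg, "optics_config"))
  1.22 * (cfg$wavelength * 1e-9) * (cfg$propagation_distance * 1e-2) /
    (cfg$spot_diameter * 1e-3) * 1e6
}

#' Average grain size of subjective (imaged) speckle
#'
#' \deqn{\delta_S = 1.22 \lambda (1 + M) f / d}
#' with focal length f, magnification M and lens aperture d. A wider lens
#' aperture gives finer speckle.
#'
#' @inheritParams objective_speckle_size
#' @return Speckle grain size in micrometres.
#' @export
subjective_speckle_size <- function(cfg) {
  stopifnot(inherits(cfg, "optics_config"))
  1.22 * (cfg$wavelength * 1e-9) * (1 + cfg$magnification) *
    (cfg$focal_length * 1e-3) / (cfg$lens_diameter * 1e-3) * 1e6
}
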