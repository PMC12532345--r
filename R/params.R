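#' OCT system parameters
#'
#' Bundles the optical and spectrometer constants that drive the axial
#' intensity model, together with the image geometry and the conversion
#' between tunable-lens diopters and focal-plane depth at the retina.
#'
#' The defaults describe a spectral-domain OCT retinal system at 810 nm with
#' an effective numerical aperture of about 0.1 in the eye (Rayleigh length
#' ~26 um), a beam quality factor emulating residual ocular aberration, and a
#' spectrometer whose pixel spacing and resolution set the sensitivity
#' roll-off. Axial pixel pitch defaults to 3 um/pixel so that the
#' quantization-limited residual of integer-pixel registration is
#' 3/sqrt(12) ~ 0.87 um.
#'
#' @param refractive_index_n Refractive index within the retina
#'   (dimensionless, ~1.38).
#' @param rayleigh_length_zR Rayleigh length of the beam at the retina, um.
#' @param beam_quality_M2 Beam quality factor M^2 (>= 1); multiplies the
#'   Rayleigh length to emulate ocular aberration.
#' @param center_wavelength_lambda0 Source center wavelength, nm.
#' @param pixel_wavelength_spacing Spectrometer wavelength spacing between
#'   pixels (capital-delta lambda), nm. Sets the maximum ranging depth
#'   `zRD = lambda0^2 / (4 * spacing)`.
#' @param spectral_resolution Spectrometer spectral resolution FWHM
#'   (small-delta lambda), nm.
#' @param mu_backscatter Power-backscattering amplitude scale (dimensionless).
#' @param mu_oct_attenuation OCT signal attenuation coefficient, 1/um.
#' @param axial_pixel_pitch Axial sampling pitch, um/pixel.
#' @param n_depth_pixels Number of depth pixels per A-scan.
#' @param n_lateral_ascans Number of lateral A-scans per B-scan.
#' @param diopter_to_depth Conversion from lens diopters to focal-depth shift
#'   at the retina, um/D. Default 370 um/D from the reduced-eye model
#'   (f_eye^2 / n_eye with f = 22.2 mm, n = 1.336).
#' @param noise_floor_sigma Standard deviation of the additive intensity
#'   noise floor, in the same (relative) intensity units as the phantom
#'   reflectivity.
#'
#' @return An object of class `oct_params` (a validated list).
#' @examples
#' p <- oct_params()
#' p$max_ranging_depth
#' @export
oct_params <- function(refractive_index_n = 1.38,
                       rayleigh_length_zR = 26,
                       beam_quality_M2 = 1.5,
                       center_wavelength_lambda0 = 810,
                       pixel_wavelength_spacing = 0.049,
                       spectral_resolution = 0.06,
                       mu_backscatter = 1,
                       mu_oct_attenuation = 0.001,
                       axial_pixel_pitch = 3,
                       n_depth_pixels = 384,
                       n_lateral_ascans = 64,
                       diopter_to_depth = 370,
                       noise_floor_sigma = 0.02) {
  p <- list(
    refractive_index_n = refractive_index_n,
    rayleigh_length_zR = rayleigh_length_zR,
    beam_quality_M2 = beam_quality_M2,
    center_wavelength_lambda0 = center_wavelength_lambda0,
    pixel_wavelength_spacing = pixel_wavelength_spacing,
    spectral_resolution = spectral_resolution,
    mu_backscatter = mu_backscatter,
    mu_oct_attenuation = mu_oct_attenuation,
    axial_pixel_pitch = axial_pixel_pitch,
    n_depth_pixels = as.integer(n_depth_pixels),
    n_lateral_ascans = as.integer(n_lateral_ascans),
    diopter_to_depth = diopter_to_depth,
    noise_floor_sigma = noise_floor_sigma
  )
  # derived spectrometer quantities; zRD in um (lambda in nm cancels)
  p$max_ranging_depth <- center_wavelength_lambda0^2 /
    (4 * pixel_wavelength_spacing) / 1000
  p$rolloff_omega <- spectral_resolution / pixel_wavelength_spacing
  class(p) <- "oct_params"
  validate_oct_params(p)
  p
}

validate_oct_params <- function(p) {
  stopifnot(
    is.finite(p$refractive_index_n), p$refractive_index_n > 0,
    is.finite(p$rayleigh_length_zR), p$rayleigh_length_zR > 0,
    is.finite(p$beam_quality_M2), p$beam_quality_M2 >= 1,
    is.finite(p$mu_oct_attenuation), p$mu_oct_attenuation >= 0,
    is.finite(p$mu_backscatter), p$mu_backscatter >= 0,
    p$pixel_wavelength_spacing > 0, p$spectral_resolution > 0,
    p$axial_pixel_pitch > 0,
    p$n_depth_pixels >= 8, p$n_lateral_ascans >= 1,
    p$diopter_to_depth > 0, p$noise_floor_sigma >= 0
  )
  if (p$rolloff_omega <= 0) stop("spectral resolution ratio must be positive")
  invisible(p)
}

#' @export
print.oct_params <- function(x, ...) {
  cat("OCT system parameters\n")
  cat(sprintf("  beam: lambda0 %.0f nm, zR %.1f um, M^2 %.2f, n %.2f\n",
              x$center_wavelength_lambda0, x$rayleigh_length_zR,
              x$beam_quality_M2, x$refractive_index_n))
  cat(sprintf("  spectrometer: dlambda %.4f nm, dlambda_res %.4f nm, zRD %.0f um, omega %.2f\n",
              x$pixel_wavelength_spacing, x$spectral_resolution,
              x$max_ranging_depth, x$rolloff_omega))
  cat(sprintf("  attenuation: muB %.3g, muOCT %.4g /um\n",
              x$mu_backscatter, x$mu_oct_attenuation))
  cat(sprintf("  image: %d x %d px, pitch %.2f um/px, %.0f um/D, noise sd %.3g\n",
              x$n_depth_pixels, x$n_lateral_ascans, x$axial_pixel_pitch,
              x$diopter_to_depth, x$noise_floor_sigma))
  invisible(x)
}

#' Ornstein-Uhlenbeck process parameters
#'
#' Parameters for mean-reverting stochastic trajectories used to emulate
#' axial head motion (um) and accommodative micro-fluctuation (diopters)
#' during an imaging session.
#'
#' `stationary_sigma` is the standard deviation of the stationary
#' distribution of the process, in the units of the driven variable; the
#' generated trajectory's long-run sample sd converges to it.
#'
#' @param mean_reversion_theta Mean-reversion rate, 1/s.
#' @param stationary_sigma Stationary standard deviation (um or D).
#' @param equilibrium_mu Equilibrium level, same units as the trajectory.
#' @param dt Step interval, s.
#' @return An object of class `ou_params`.
#' @examples
#' ou_params(stationary_sigma = 53.2)
#' @export
ou_params <- function(mean_reversion_theta = 5,
                      stationary_sigma = 1,
                      equilibrium_mu = 0,
                      dt = 0.04) {
  stopifnot(is.finite(mean_reversion_theta), mean_reversion_theta > 0,
            is.finite(stationary_sigma), stationary_sigma >= 0,
            is.finite(equilibrium_mu), is.finite(dt), dt > 0)
  structure(list(mean_reversion_theta = mean_reversion_theta,
                 stationary_sigma = stationary_sigma,
                 equilibrium_mu = equilibrium_mu,
                 dt = dt),
            class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf("OU process: theta %.3g /s, stationary sd %.3g, mu %.3g, dt %.3g s\n",
              x$mean_reversion_theta, x$stationary_sigma,
              x$equilibrium_mu, x$dt))
  invisible(x)
}

#' Focus state of a rendered frame
#'
#' Describes the rigid axial displacement of the retina and the focal-plane
#' position used to render a frame. The focal depth follows
#' `focal_depth_zf = reference_zf + defocus_diopters * diopter_to_depth`
#' in retina-anchored coordinates; rigid motion shifts retina and focus
#' together (the renderer adds `axial_shift` to both), because head motion
#' moves the whole eye, optics included.
#'
#' @param reference_zf Reference focal depth within the image, um.
#' @param defocus_diopters Defocus relative to the reference focus, D.
#' @param axial_shift Rigid axial displacement of the retina, um
#'   (positive = deeper).
#' @param params An [oct_params()] object supplying `diopter_to_depth`.
#' @return An object of class `focus_state` with fields `focal_depth_zf`,
#'   `axial_shift` and `defocus_diopters`.
#' @export
focus_state <- function(reference_zf, defocus_diopters = 0, axial_shift = 0,
                        params = oct_params()) {
  stopifnot(is.finite(reference_zf), is.finite(defocus_diopters),
            is.finite(axial_shift))
  structure(list(
    reference_zf = reference_zf,
    defocus_diopters = defocus_diopters,
    axial_shift = axial_shift,
    focal_depth_zf = reference_zf + defocus_diopters * params$diopter_to_depth
  ), class = "focus_state")
}
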