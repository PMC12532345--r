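#' Confocal point spread function (axial collection efficiency)
#'
#' Axial weighting of a Gaussian-beam confocal system with diffuse
#' reflection:
#' `T(z - zf) = 1 / ( ((z - zf) / (2 n zR_eff))^2 + 1 )`,
#' where `zR_eff = M^2 * zR` inflates the Rayleigh length by the beam
#' quality factor to emulate residual ocular aberration. Maximum 1 at the
#' focal plane; half maximum at `|z - zf| = 2 n zR_eff`.
#'
#' @param z Depth position(s), um.
#' @param zf Focal-plane depth, um.
#' @param params An [oct_params()] object.
#' @return Dimensionless weight(s) in (0, 1].
#' @export
cpsf <- function(z, zf, params = oct_params()) {
  if (!all(is.finite(z)) || !all(is.finite(zf)))
    stop("cpsf: non-finite depth input")
  zr_eff <- params$beam_quality_M2 * params$rayleigh_length_zR
  1 / (((z - zf) / (2 * params$refractive_index_n * zr_eff))^2 + 1)
}

#' Depth attenuation by absorption and scattering
#'
#' Exponential single-scattering decay
#' `A(z) = muB * exp(-2 * muOCT * z)` with `z` the depth into the tissue
#' measured from the retina inner surface, um.
#'
#' @param z Tissue depth(s) >= 0, um.
#' @param params An [oct_params()] object.
#' @return Dimensionless amplitude weight(s).
#' @export
attenuation <- function(z, params = oct_params()) {
  if (!all(is.finite(z))) stop("attenuation: non-finite depth input")
  params$mu_backscatter * exp(-2 * params$mu_oct_attenuation * z)
}

#' Spectral-domain OCT sensitivity roll-off
#'
#' Depth-dependent sensitivity decay set by the spectrometer pixel spacing
#' and spectral resolution:
#' `H(z) = sinc^2(pi z / 2 zRD) * exp(-pi^2 omega^2 / (8 ln 2) * (z/zRD)^2)`
#' with `zRD = lambda0^2 / (4 dlambda)` the maximum ranging depth and
#' `omega = dlambda_res / dlambda`. `H(0) = 1` by the analytic limit.
#'
#' @param z Depth position(s) >= 0, um.
#' @param params An [oct_params()] object.
#' @return Weight(s) in `[0, 1]`.
#' @export
sensitivity_rolloff <- function(z, params = oct_params()) {
  if (!all(is.finite(z))) stop("sensitivity_rolloff: non-finite depth input")
  zrd <- params$max_ranging_depth
  x <- pi * z / (2 * zrd)
  sinc2 <- ifelse(abs(x) < 1e-8, 1, (sin(x) / x)^2)
  gauss <- exp(-pi^2 * params$rolloff_omega^2 / (8 * log(2)) * (z / zrd)^2)
  sinc2 * gauss
}

# shift a profile by a (possibly fractional) number of pixels;
# positive shift moves content deeper; out-of-window samples get fill values
shift_profile <- function(x, shift_px, fill_top, fill_bottom = fill_top) {
  n <- length(x)
  y <- stats::approx(seq_len(n), x, xout = seq_len(n) - shift_px,
                     rule = 1)$y
  idx_top <- seq_len(n) - shift_px < 1
  y[idx_top] <- fill_top
  y[seq_len(n) - shift_px > n] <- fill_bottom
  y
}

#' Simulated axial intensity profile of a defocused retina
#'
#' Renders a single A-scan `I(z; zf)` as the product of the (axially
#' shifted) retina reflectivity, the confocal point spread function at the
#' focal depth, tissue attenuation and spectrometer sensitivity roll-off,
#' plus an additive Gaussian noise floor clamped to nonnegative intensity.
#'
#' Attenuation and the focal plane are evaluated in retina-anchored
#' coordinates: rigid axial motion displaces the whole eye (retina and its
#' optics together), so the image shifts but the focus-to-retina
#' relationship does not — `focal_depth_zf` is the focal depth for an
#' unshifted retina and the renderer adds `axial_shift` to it. Only the
#' spectrometer roll-off stays fixed in image coordinates (it is an
#' instrument property). Sub-pixel shifts are rendered by linear
#' interpolation; out-of-window samples are filled with the (attenuated)
#' background level.
#'
#' @param phantom A [make_phantom()] object.
#' @param state A [focus_state()] object.
#' @param params An [oct_params()] object.
#' @param rng_seed Optional integer seed for the noise draw.
#' @param noise If `FALSE`, omit the additive noise term.
#' @return Numeric vector of length `params$n_depth_pixels`.
#' @export
compose_axial_intensity <- function(phantom, state, params = oct_params(),
                                    rng_seed = NULL, noise = TRUE) {
  n <- params$n_depth_pixels
  if (length(phantom$reflectivity_R) != n)
    stop("phantom length does not match n_depth_pixels")
  window_um <- n * params$axial_pixel_pitch
  if (abs(state$axial_shift) >= window_um)
    stop("axial shift moves the retina fully out of the imaging window")
  z_um <- (seq_len(n) - 1) * params$axial_pixel_pitch
  base <- phantom$reflectivity_R * attenuation(z_um, params)
  shift_px <- state$axial_shift / params$axial_pixel_pitch
  shifted <- shift_profile(base, shift_px,
                           fill_top = phantom$background_level *
                             attenuation(0, params),
                           fill_bottom = phantom$background_level *
                             attenuation(max(z_um), params))
  i <- shifted * cpsf(z_um, state$focal_depth_zf + state$axial_shift, params) *
    sensitivity_rolloff(z_um, params)
  if (noise && params$noise_floor_sigma > 0) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    i <- i + stats::rnorm(n, 0, params$noise_floor_sigma)
  }
  pmax(i, 0)
}

#' Render a simulated B-scan
#'
#' Extends [compose_axial_intensity()] to a 2D B-scan by replicating the
#' axial profile across lateral positions with small per-column
#' multiplicative gain variation and independent per-pixel noise. All
#' columns share the same reflectivity and focus state.
#'
#' @param phantom A [make_phantom()] object.
#' @param state A [focus_state()] object.
#' @param params An [oct_params()] object.
#' @param lateral_variation Standard deviation of the per-column gain about 1.
#' @param rng_seed Optional integer seed (covers gains and noise).
#' @param noise If `FALSE`, omit gain jitter and additive noise.
#' @return An object of class `bscan`: list with `intensity`
#'   (depth x lateral matrix) and `meta` (the focus state).
#' @export
render_bscan <- function(phantom, state, params = oct_params(),
                         lateral_variation = 0.05, rng_seed = NULL,
                         noise = TRUE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  clean <- compose_axial_intensity(phantom, state, params, noise = FALSE)
  nl <- params$n_lateral_ascans
  img <- matrix(clean, nrow = params$n_depth_pixels, ncol = nl)
  if (noise) {
    if (lateral_variation > 0) {
      gains <- 1 + stats::rnorm(nl, 0, lateral_variation)
      img <- sweep(img, 2, gains, `*`)
    }
    if (params$noise_floor_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0,
                                       params$noise_floor_sigma),
                          nrow = nrow(img))
  }
  structure(list(intensity = pmax(img, 0), meta = state), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("OCT B-scan: %d depth px x %d A-scans, zf %.1f um, shift %.1f um, defocus %.3f D\n",
              nrow(x$intensity), ncol(x$intensity),
              x$meta$focal_depth_zf, x$meta$axial_shift,
              x$meta$defocus_diopters))
  invisible(x)
}

#' Ornstein-Uhlenbeck trajectory
#'
#' Simulates a mean-reverting trajectory using the exact AR(1)
#' discretization of the OU process, initialized from the stationary
#' distribution, so the long-run sample standard deviation matches the
#' configured `stationary_sigma` for any `theta * dt`.
#'
#' @param params An [ou_params()] object.
#' @param n_steps Number of samples (>= 1).
#' @param rng_seed Optional integer seed.
#' @return Numeric vector of length `n_steps`.
#' @export
ou_trajectory <- function(params, n_steps, rng_seed = NULL) {
  stopifnot(inherits(params, "ou_params"), n_steps >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  mu <- params$equilibrium_mu
  s <- params$stationary_sigma
  if (s == 0) return(rep(mu, n_steps))
  a <- exp(-params$mean_reversion_theta * params$dt)
  x0 <- stats::rnorm(1, 0, s)
  if (n_steps == 1) return(mu + x0)
  innov <- stats::rnorm(n_steps - 1, 0, s * sqrt(1 - a^2))
  dev <- stats::filter(innov, a, method = "recursive", init = x0)
  mu + c(x0, as.numeric(dev))
}
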