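#' Synthetic retina reflectivity phantom
#'
#' Builds an axial reflectivity profile `R(z)` with two Gaussian-profile
#' bright bands over a low background: a shallower "inner retina" band and a
#' deeper, typically brighter "outer retina" band. A single-band "foveal"
#' variant (outer band only) is available for regions where only the outer
#' retina is bright.
#'
#' Band centers are in depth pixels; widths are Gaussian standard deviations
#' in pixels. Randomization (`jitter_frac > 0`) perturbs centers, widths and
#' amplitudes for generalization tests.
#'
#' @param n_depth_pixels Profile length in pixels.
#' @param inner_band_center,outer_band_center Band centers, depth pixels
#'   (outer must be deeper than inner).
#' @param inner_band_width,outer_band_width Gaussian sd of each band, pixels.
#' @param inner_band_amplitude,outer_band_amplitude Peak reflectivity of each
#'   band above background (relative units).
#' @param background_level Baseline reflectivity (relative units).
#' @param foveal If `TRUE`, drop the inner band (single-peak phantom).
#' @param jitter_frac Relative jitter applied to band centers, widths and
#'   amplitudes (0 = deterministic phantom).
#' @param rng_seed Optional integer seed used when `jitter_frac > 0`.
#' @return An object of class `retina_phantom`: list with `reflectivity_R`
#'   (nonnegative numeric vector), band geometry fields and
#'   `background_level`.
#' @examples
#' ph <- make_phantom()
#' plot(ph)
#' @export
make_phantom <- function(n_depth_pixels = 384,
                         inner_band_center = 140,
                         outer_band_center = 220,
                         inner_band_width = 7,
                         outer_band_width = 5,
                         inner_band_amplitude = 0.9,
                         outer_band_amplitude = 1.0,
                         background_level = 0.05,
                         foveal = FALSE,
                         jitter_frac = 0,
                         rng_seed = NULL) {
  stopifnot(n_depth_pixels >= 8,
            outer_band_center > inner_band_center,
            inner_band_width > 0, outer_band_width > 0,
            inner_band_amplitude >= 0, outer_band_amplitude > 0,
            background_level >= 0, jitter_frac >= 0)
  if (jitter_frac > 0) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    jit <- function(x) x * (1 + stats::runif(1, -jitter_frac, jitter_frac))
    inner_band_center <- jit(inner_band_center)
    outer_band_center <- jit(outer_band_center)
    inner_band_width <- jit(inner_band_width)
    outer_band_width <- jit(outer_band_width)
    inner_band_amplitude <- jit(inner_band_amplitude)
    outer_band_amplitude <- jit(outer_band_amplitude)
    if (outer_band_center <= inner_band_center + 4 * inner_band_width)
      outer_band_center <- inner_band_center + 4 * inner_band_width + 10
  }
  z <- seq_len(n_depth_pixels)
  r <- rep(background_level, n_depth_pixels)
  if (!foveal)
    r <- r + inner_band_amplitude *
      exp(-0.5 * ((z - inner_band_center) / inner_band_width)^2)
  r <- r + outer_band_amplitude *
    exp(-0.5 * ((z - outer_band_center) / outer_band_width)^2)
  structure(list(
    reflectivity_R = r,
    inner_band_center = if (foveal) NA_real_ else inner_band_center,
    outer_band_center = outer_band_center,
    inner_band_width = if (foveal) NA_real_ else inner_band_width,
    outer_band_width = outer_band_width,
    inner_band_amplitude = if (foveal) 0 else inner_band_amplitude,
    outer_band_amplitude = outer_band_amplitude,
    background_level = background_level,
    foveal = foveal
  ), class = "retina_phantom")
}

#' @export
print.retina_phantom <- function(x, ...) {
  if (x$foveal) {
    cat(sprintf("Foveal retina phantom: %d px, outer band at %.0f px (sd %.1f px)\n",
                length(x$reflectivity_R), x$outer_band_center, x$outer_band_width))
  } else {
    cat(sprintf("Two-band retina phantom: %d px, inner %.0f px (a=%.2f), outer %.0f px (a=%.2f)\n",
                length(x$reflectivity_R), x$inner_band_center,
                x$inner_band_amplitude, x$outer_band_center,
                x$outer_band_amplitude))
  }
  invisible(x)
}

#' @export
plot.retina_phantom <- function(x, ...) {
  graphics::plot(x$reflectivity_R, type = "l",
                 xlab = "depth (pixels)", ylab = "reflectivity R(z)",
                 main = "Retina phantom", ...)
  invisible(x)
}
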