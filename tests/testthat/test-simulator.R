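test_that("confocal PSF hits its closed-form landmarks", {
  p <- test_params()
  zr_eff <- p$beam_quality_M2 * p$rayleigh_length_zR
  half_off <- 2 * p$refractive_index_n * zr_eff
  expect_equal(cpsf(500, 500, p), 1)
  expect_equal(cpsf(500 + half_off, 500, p), 0.5)
  expect_equal(cpsf(500 - half_off, 500, p), 0.5)
  # symmetric, strictly decreasing away from focus
  off <- seq(0, 400, by = 10)
  expect_equal(cpsf(500 + off, 500, p), cpsf(500 - off, 500, p))
  expect_true(all(diff(cpsf(500 + off, 500, p)) < 0))
  expect_error(cpsf(NaN, 500, p), "non-finite")
})

test_that("attenuation follows the exponential decay law", {
  p <- test_params(mu_backscatter = 2.5, mu_oct_attenuation = 0.002)
  expect_equal(attenuation(0, p), 2.5)
  expect_equal(attenuation(log(2) / (2 * 0.002), p), 2.5 / 2)
  p0 <- test_params(mu_oct_attenuation = 0)
  expect_equal(attenuation(c(0, 100, 1000), p0),
               rep(p0$mu_backscatter, 3))
  z <- seq(0, 1000, by = 50)
  expect_true(all(diff(attenuation(z, p)) < 0))
})

test_that("sensitivity roll-off has the analytic limit and sinc landmark", {
  p <- test_params()
  zrd <- p$max_ranging_depth
  expect_equal(sensitivity_rolloff(0, p), 1)
  sinc_factor <- sensitivity_rolloff(zrd, p) /
    exp(-pi^2 * p$rolloff_omega^2 / (8 * log(2)))
  expect_equal(sinc_factor, 4 / pi^2)
  # monotone non-increasing on [0, zRD] on a dense grid
  h <- sensitivity_rolloff(seq(0, zrd, length.out = 2000), p)
  expect_true(all(diff(h) <= 1e-12))
  expect_true(all(h >= 0 & h <= 1))
})

test_that("axial intensity factorizes as reflectivity times CPSF when other factors are flat", {
  # kill attenuation, noise and (via a huge ranging depth at fixed omega)
  # roll-off
  p <- test_params(mu_oct_attenuation = 0, noise_floor_sigma = 0,
                   pixel_wavelength_spacing = 1e-9,
                   spectral_resolution = 1e-12)
  ph <- test_phantom()
  zf <- (ph$outer_band_center - 1) * p$axial_pixel_pitch
  st <- focus_state(zf, 0, 0, p)
  i <- compose_axial_intensity(ph, st, p, noise = FALSE)
  z <- (seq_len(p$n_depth_pixels) - 1) * p$axial_pixel_pitch
  expect_equal(i, ph$reflectivity_R * cpsf(z, zf, p), tolerance = 1e-12)
})

test_that("defocus redistributes intensity between the retinal bands", {
  p <- test_params(noise_floor_sigma = 0)
  ph <- test_phantom()
  band_peak <- function(i, ctr) max(i[(ctr - 15):(ctr + 15)])
  ratio_at <- function(zf_px) {
    st <- focus_state((zf_px - 1) * p$axial_pixel_pitch, 0, 0, p)
    i <- compose_axial_intensity(ph, st, p, noise = FALSE)
    band_peak(i, ph$inner_band_center) / band_peak(i, ph$outer_band_center)
  }
  r_inner <- ratio_at(ph$inner_band_center)
  r_outer <- ratio_at(ph$outer_band_center)
  expect_gt(r_inner, r_outer)
  # monotone decreasing as the focus sweeps from inner to outer band
  sweep_px <- seq(ph$inner_band_center, ph$outer_band_center, by = 8)
  ratios <- vapply(sweep_px, ratio_at, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("rendering is deterministic given a seed and shift rolls the image", {
  p <- test_params()
  ph <- test_phantom()
  st <- focus_state(500, 0.2, 40, p)
  expect_identical(compose_axial_intensity(ph, st, p, rng_seed = 11),
                   compose_axial_intensity(ph, st, p, rng_seed = 11))
  b1 <- render_bscan(ph, st, p, rng_seed = 5)
  b2 <- render_bscan(ph, st, p, rng_seed = 5)
  expect_identical(b1$intensity, b2$intensity)
  # zero lateral variation and zero noise: all columns equal the profile
  p0 <- test_params(noise_floor_sigma = 0)
  b0 <- render_bscan(ph, st, p0, lateral_variation = 0, noise = FALSE)
  expect_equal(b0$intensity,
               matrix(compose_axial_intensity(ph, st, p0, noise = FALSE),
                      nrow = p0$n_depth_pixels, ncol = p0$n_lateral_ascans))
  # integer shift of the reflectivity (flat focus factors) = rolled render
  pf <- test_params(mu_oct_attenuation = 0, noise_floor_sigma = 0,
                    pixel_wavelength_spacing = 1e-9,
                    spectral_resolution = 1e-12,
                    rayleigh_length_zR = 1e7)
  k <- 12
  i0 <- compose_axial_intensity(ph, focus_state(500, 0, 0, pf), pf,
                                noise = FALSE)
  ik <- compose_axial_intensity(ph,
                                focus_state(500, 0, k * pf$axial_pixel_pitch,
                                            pf),
                                pf, noise = FALSE)
  expect_equal(ik[(k + 1):pf$n_depth_pixels],
               i0[1:(pf$n_depth_pixels - k)], tolerance = 1e-10)
  # a shift beyond the window is rejected
  expect_error(compose_axial_intensity(
    ph, focus_state(500, 0, 2000 * pf$axial_pixel_pitch, pf), pf),
    "out of the imaging window")
})

test_that("OU trajectories are stationary at the configured sd and reproducible", {
  ou <- ou_params(mean_reversion_theta = 0.5, stationary_sigma = 53.2,
                  dt = 0.04)
  x <- ou_trajectory(ou, 1e5, rng_seed = 1)
  expect_lt(abs(stats::sd(x) - 53.2) / 53.2, 0.05)
  expect_lt(abs(mean(x)), 5)
  expect_identical(x, ou_trajectory(ou, 1e5, rng_seed = 1))
  # zero sigma collapses to the equilibrium
  expect_equal(ou_trajectory(ou_params(stationary_sigma = 0,
                                       equilibrium_mu = 3), 50),
               rep(3, 50))
  expect_error(ou_params(mean_reversion_theta = -1))
})

test_that("phantoms have the advertised band structure", {
  ph <- test_phantom()
  r <- ph$reflectivity_R
  peaks <- which(r[2:383] > r[1:382] & r[2:383] > r[3:384]) + 1
  peaks <- peaks[r[peaks] > ph$background_level + 0.1]
  expect_length(peaks, 2)
  expect_equal(peaks, c(ph$inner_band_center, ph$outer_band_center))
  fov <- test_phantom(foveal = TRUE)
  rf <- fov$reflectivity_R
  pf <- which(rf[2:383] > rf[1:382] & rf[2:383] > rf[3:384]) + 1
  pf <- pf[rf[pf] > fov$background_level + 0.1]
  expect_length(pf, 1)
  # peak ratio equals the amplitude ratio (up to the small background)
  ph2 <- make_phantom(inner_band_amplitude = 0.5, outer_band_amplitude = 1,
                      background_level = 0)
  expect_equal(max(ph2$reflectivity_R[1:180]) /
                 max(ph2$reflectivity_R[181:384]), 0.5, tolerance = 1e-6)
  expect_true(all(ph$reflectivity_R >= 0))
})
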