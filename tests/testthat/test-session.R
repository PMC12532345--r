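test_that("session metrics are plain sample statistics", {
  tr <- data.frame(t = c(0, 0.04, 0.08),
                   applied_shift_um = c(10, 10, 10),
                   applied_defocus_D = c(0.1, 0.1, 0.1),
                   corrected_shift_um = c(11, 10, 9),
                   corrected_defocus_D = c(0.1, 0.1, 0.1),
                   residual_shift_um = c(-1, 0, 1),
                   residual_defocus_D = c(0, 0, 0),
                   reward = c(-0.1, -0.1, -0.1))
  class(tr) <- c("session_trace", "data.frame")
  m <- session_metrics(tr)
  expect_equal(m$std_residual_shift_um, 1)   # sd with n - 1 denominator
  expect_equal(m$std_applied_shift_um, 0)
  expect_equal(m$std_residual_defocus_D, 0)
  expect_equal(m$mean_abs_residual_shift_um, 2 / 3)
})

test_that("traces round-trip through CSV", {
  tr <- data.frame(t = c(0, 0.04), applied_shift_um = c(1.5, -2.25),
                   applied_defocus_D = c(0.12, -0.05),
                   corrected_shift_um = c(0, -3),
                   corrected_defocus_D = c(0.1, -0.04),
                   residual_shift_um = c(1.5, 0.75),
                   residual_defocus_D = c(0.02, -0.01),
                   reward = c(-0.3, -0.2))
  class(tr) <- c("session_trace", "data.frame")
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_s3_class(back, "session_trace")
  expect_equal(as.data.frame(back), as.data.frame(tr))
  m1 <- session_metrics(tr)
  m2 <- session_metrics(back)
  expect_equal(m1, m2)
  unlink(path)
})

test_that("kymographs are depth-by-time projections", {
  stack <- list(matrix(1, 10, 4), matrix(2, 10, 4), matrix(3, 10, 4))
  ky <- kymograph(stack)
  expect_equal(dim(ky), c(10, 3))
  expect_equal(ky[, 2], rep(2, 10))
  # identical frames give constant columns
  ky2 <- kymograph(list(matrix(1:10, 10, 2), matrix(1:10, 10, 2)))
  expect_equal(ky2[, 1], ky2[, 2])
})

test_that("kymograph band-ratio variability collapses under full correction", {
  p <- test_params()
  ph <- test_phantom()
  set.seed(77)
  zf_mid <- phantom_mid_zf_test(ph, p)
  defocus <- ou_trajectory(ou_params(stationary_sigma = 0.27), 30)
  motion <- ou_trajectory(ou_params(stationary_sigma = 53.2), 30)
  ref <- render_bscan(ph, focus_state(zf_mid, 0, 0, p), p)
  motion_only <- list()
  fully_corr <- list()
  for (i in 1:30) {
    tgt <- render_bscan(ph, focus_state(zf_mid, defocus[i], motion[i], p), p)
    reg <- register_axial(ref, tgt, params = p)
    motion_only[[i]] <- apply_axial_correction(tgt, reg$shift_pixels)
    # oracle focus correction: re-render with the defocus removed
    fixed <- render_bscan(ph, focus_state(zf_mid, 0, motion[i], p), p)
    fully_corr[[i]] <- apply_axial_correction(fixed, reg$shift_pixels)
  }
  band_ratio_series <- function(stack) {
    ky <- kymograph(stack)
    apply(ky, 2, function(a)
      max(a[(ph$inner_band_center - 10):(ph$inner_band_center + 10)]) /
        max(a[(ph$outer_band_center - 10):(ph$outer_band_center + 10)]))
  }
  sd_motion_only <- stats::sd(band_ratio_series(motion_only))
  sd_full <- stats::sd(band_ratio_series(fully_corr))
  expect_gt(sd_motion_only, 10 * sd_full)
})

test_that("sessions are deterministic given a seed and record per-frame state", {
  agent <- make_untrained_agent()
  ses1 <- run_session(agent, n_frames = 6, rng_seed = 99,
                      ou_motion = ou_params(stationary_sigma = 40),
                      ou_defocus = ou_params(stationary_sigma = 0.2))
  ses2 <- run_session(agent, n_frames = 6, rng_seed = 99,
                      ou_motion = ou_params(stationary_sigma = 40),
                      ou_defocus = ou_params(stationary_sigma = 0.2))
  expect_equal(ses1$trace, ses2$trace)
  expect_equal(nrow(ses1$trace), 6)
  expect_equal(ses1$trace$residual_shift_um,
               ses1$trace$applied_shift_um - ses1$trace$corrected_shift_um)
  expect_equal(ses1$trace$residual_defocus_D,
               ses1$trace$applied_defocus_D - ses1$trace$corrected_defocus_D)
  # registration alone keeps the residual within the pixel quantization
  # plus the occasional single-pixel slip
  expect_true(all(abs(ses1$trace$residual_shift_um) <=
                    2 * agent$params$axial_pixel_pitch))
})

test_that("zero-amplitude disturbances leave motion residuals at zero", {
  agent <- make_untrained_agent()
  ses <- run_session(agent, n_frames = 4, rng_seed = 5,
                     ou_motion = ou_params(stationary_sigma = 0),
                     ou_defocus = ou_params(stationary_sigma = 0))
  expect_equal(ses$trace$applied_shift_um, rep(0, 4))
  expect_equal(ses$trace$corrected_shift_um, rep(0, 4))
  expect_equal(ses$trace$residual_shift_um, rep(0, 4))
  # an untrained actor near tanh init outputs a small correction; the
  # residual defocus equals its negation exactly
  expect_equal(ses$trace$residual_defocus_D,
               -ses$trace$corrected_defocus_D)
})

test_that("B-scan stacks round-trip through multi-page TIFF", {
  p <- test_params(n_depth_pixels = 64L, n_lateral_ascans = 8L)
  ph <- make_phantom(n_depth_pixels = 64, inner_band_center = 24,
                     outer_band_center = 40)
  b1 <- render_bscan(ph, focus_state(100, 0, 0, p), p, rng_seed = 1)
  b2 <- render_bscan(ph, focus_state(100, 0.2, 9, p), p, rng_seed = 2)
  path <- tempfile(fileext = ".tiff")
  write_bscan_stack(list(b1, b2), path)
  back <- read_bscan_stack(path)
  expect_length(back, 2)
  mx <- max(b1$intensity, b2$intensity)
  expect_equal(back[[1]], b1$intensity / mx, tolerance = 1e-6)
  expect_equal(back[[2]], b2$intensity / mx, tolerance = 1e-6)
  unlink(path)
})

test_that("config files build the full parameter set", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "params:",
    "  axial_pixel_pitch: 2.5",
    "  n_depth_pixels: 256",
    "phantom:",
    "  n_depth_pixels: 256",
    "  inner_band_center: 90",
    "  outer_band_center: 170",
    "ou_motion:",
    "  stationary_sigma: 53.2",
    "ou_defocus:",
    "  stationary_sigma: 0.27",
    "agent:",
    "  train_steps: 10"
  ), path)
  cfg <- read_config(path)
  expect_equal(cfg$params$axial_pixel_pitch, 2.5)
  expect_equal(cfg$params$n_depth_pixels, 256L)
  expect_equal(length(cfg$phantom$reflectivity_R), 256)
  expect_equal(cfg$ou_motion$stationary_sigma, 53.2)
  expect_equal(cfg$ou_defocus$stationary_sigma, 0.27)
  expect_equal(cfg$agent$train_steps, 10L)
  unlink(path)
})
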