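test_that("the ED similarity metric matches direct computation", {
  expect_equal(ed_metric(c(1, 0, 0, 0), c(0, 0, 0, 1)), -sqrt(2 / 4))
  x <- runif(32)
  expect_equal(ed_metric(x, x), 0)
  y <- runif(32)
  expect_equal(ed_metric(x, y), ed_metric(y, x))
  expect_lte(ed_metric(x, y), 0)
})

test_that("EDM construction flags flat input and localizes edges", {
  e0 <- compute_edm(rep(3, 100))
  expect_true(e0$degenerate)
  expect_equal(e0$edm, rep(0, 100))
  # step edge: one dominant peak near the edge
  step <- c(rep(0, 60), rep(1, 60))
  e <- compute_edm(step, sigma = 3)
  expect_false(e$degenerate)
  expect_equal(max(e$edm), 1)
  expect_lt(abs(which.max(e$edm) - 60.5), 3 + 1)
  # two-band phantom: peak clusters bracket both band centers
  p <- test_params(noise_floor_sigma = 0)
  ph <- test_phantom()
  st <- focus_state(phantom_mid_zf_test(ph, p), 0, 0, p)
  a <- compose_axial_intensity(ph, st, p, noise = FALSE)
  edm <- compute_edm(a, sigma = 3)
  cl <- edm$clusters
  expect_gte(nrow(cl), 2)
  expect_true(any(cl$from < ph$inner_band_center &
                    cl$to > ph$inner_band_center))
  expect_true(any(cl$from < ph$outer_band_center &
                    cl$to > ph$outer_band_center))
})

test_that("inner-retina masking removes the shallow band and is idempotent", {
  p <- test_params(noise_floor_sigma = 0)
  ph <- test_phantom()
  st <- focus_state(phantom_mid_zf_test(ph, p), 0, 0, p)
  a <- compose_axial_intensity(ph, st, p, noise = FALSE)
  edm <- compute_edm(a, sigma = 3)
  masked <- mask_inner_retina(edm)
  expect_true(masked$mask_applied)
  # zero left of the inter-band valley, outer edges kept
  expect_true(all(masked$edm[1:ph$inner_band_center] == 0))
  expect_gt(max(masked$edm[(ph$outer_band_center - 10):
                             (ph$outer_band_center + 10)]), 0.5)
  # idempotent
  again <- mask_inner_retina(masked)
  expect_equal(again$edm, masked$edm)
  # single-band (foveal) profile passes through unmasked
  fov <- test_phantom(foveal = TRUE)
  af <- compose_axial_intensity(fov,
                                focus_state((fov$outer_band_center - 1) * 3,
                                            0, 0, p),
                                p, noise = FALSE)
  ef <- compute_edm(af, sigma = 3)
  mf <- mask_inner_retina(ef)
  expect_false(mf$mask_applied)
  expect_equal(mf$edm, ef$edm)
})

test_that("pixel-shift search recovers pure shifts exactly (roll oracle)", {
  p <- test_params()
  ph <- test_phantom()
  set.seed(10)
  ref <- render_bscan(ph, focus_state(phantom_mid_zf_test(ph, p), 0, 0, p), p)
  n <- p$n_depth_pixels
  for (k in c(-40, -13, 0, 5, 29, 60)) {
    # target = reference image rolled axially by k pixels (background fill)
    fill <- stats::quantile(ref$intensity, 0.25, names = FALSE)
    img <- matrix(fill, n, ncol(ref$intensity))
    if (k >= 0) img[(1 + k):n, ] <- ref$intensity[1:(n - k), ]
    else img[1:(n + k), ] <- ref$intensity[(1 - k):n, ]
    reg <- register_axial(ref$intensity, img, params = p)
    expect_identical(reg$shift_pixels, as.integer(k))
    expect_equal(length(reg$metric_curve), 2L * reg$Np + 1L)
    expect_equal(reg$best_metric, max(reg$metric_curve))
    # applying the correction restores alignment
    back <- apply_axial_correction(img, reg$shift_pixels)
    inner <- (abs(k) + 2):(n - abs(k) - 2)
    expect_equal(back[inner, ], ref$intensity[inner, ], tolerance = 1e-10)
  }
})

test_that("a shift beyond the search range clamps to the boundary", {
  p <- test_params()
  ph <- test_phantom()
  set.seed(3)
  ref <- render_bscan(ph, focus_state(phantom_mid_zf_test(ph, p), 0, 0, p), p)
  n <- p$n_depth_pixels
  k <- 30
  fill <- stats::quantile(ref$intensity, 0.25, names = FALSE)
  img <- matrix(fill, n, ncol(ref$intensity))
  img[(1 + k):n, ] <- ref$intensity[1:(n - k), ]
  reg_small <- register_axial(ref$intensity, img, Np = 10, params = p)
  expect_equal(abs(reg_small$shift_pixels), 10L)
  reg_full <- register_axial(ref$intensity, img, params = p)
  expect_lt(reg_small$best_metric, reg_full$best_metric)
})

test_that("masking disambiguates cross-focus pairs where raw profiles mislead", {
  p <- test_params()
  ph <- test_phantom()
  set.seed(42)
  n_pairs <- 40
  masked_err <- numeric(n_pairs)
  raw_err <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    k <- sample(-60:60, 1)
    pair <- make_crossfocus_pair(ph, p, k,
                                 ref_band = sample(c("inner", "outer"), 1),
                                 tgt_band = sample(c("inner", "outer"), 1))
    rm <- register_axial(pair$ref, pair$tgt, params = p)
    rr <- register_axial(pair$ref, pair$tgt, profile = "raw", params = p)
    masked_err[i] <- abs(rm$shift_pixels - k)
    raw_err[i] <- abs(rr$shift_pixels - k)
  }
  # masked-EDM registration never confuses the bands: every error is within
  # the 1-px apparent-edge shift that strong cross-focus CPSF weighting
  # induces, and most pairs are exact; raw-profile ED misaligns the bands
  # (gross, > 5 px) on a nonzero fraction of the same pairs
  expect_true(all(masked_err <= 1))
  expect_gte(mean(masked_err == 0), 0.5)
  expect_gt(mean(raw_err > 5), 0)
})

test_that("registering two flat frames is reported un-registrable", {
  flat <- matrix(1, 100, 8)
  expect_error(register_axial(flat, flat), "un-registrable")
})
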