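test_that("sliding-window reward is zero for matched or window-shifted profiles", {
  set.seed(4)
  a <- sin(seq(0, 6 * pi, length.out = 128)) + 2
  expect_equal(reward_focus(a, a, Nb = 15), 0)
  # cyclic roll within the window is forgiven
  for (k in c(-10, 4, 15)) {
    rolled <- a[((seq_along(a) - 1 - k) %% length(a)) + 1]
    expect_equal(reward_focus(a, rolled, Nb = 15), 0, tolerance = 1e-12)
  }
  # Nb = 0 equals the direct normalized ED; brute force confirms the window
  b <- a + 0.3 * cos(seq(0, 4 * pi, length.out = 128))
  np <- normalize_pair(a, b)
  expect_equal(reward_focus(a, b, Nb = 0), ed_metric(np$ref_norm, np$tgt_norm))
  # brute-force sliding minimum (independent loop) matches reward_focus
  brute <- -Inf
  n <- length(a)
  for (s in -15:15) {
    i <- max(1, 1 - s):min(n, n - s)
    brute <- max(brute, -sqrt(mean((np$ref_norm[i] - np$tgt_norm[i + s])^2)))
  }
  expect_equal(reward_focus(a, b, Nb = 15), brute)
  expect_lte(reward_focus(a, b, Nb = 15), 0)
  # invariance to joint positive rescaling
  expect_equal(reward_focus(10 * a, 10 * b, Nb = 5),
               reward_focus(a, b, Nb = 5))
  expect_error(reward_focus(rep(1, 50), rep(1, 50)), "degenerate")
})

test_that("window tolerance decays only beyond Nb", {
  a <- exp(-0.5 * ((1:128 - 64) / 6)^2)
  roll <- function(x, k) x[((seq_along(x) - 1 - k) %% length(x)) + 1]
  r_within <- reward_focus(a, roll(a, 8), Nb = 10)
  r_beyond <- reward_focus(a, roll(a, 25), Nb = 10)
  expect_gte(r_within, r_beyond)
  expect_equal(r_within, 0, tolerance = 1e-12)
  expect_lt(r_beyond, -0.1)
})

test_that("actor output is bounded, deterministic and the trunk has the specified size", {
  set.seed(5)
  actor <- octfocus:::build_actor(8L, 512L)
  obs <- matrix(rnorm(8 * 512), 8, 512)
  a1 <- octfocus:::actor_forward(actor, obs)
  expect_length(a1, 1)
  expect_true(a1 > -1 && a1 < 1)
  expect_identical(a1, octfocus:::actor_forward(actor, obs))
  # hand-computed parameter count for 8 channels x 512 depth:
  # conv 8->16 k3 (400) + conv 16->32 k3 (1568); 512 -> 510 -> 255 -> 253
  # -> 126 -> flatten 4032; fc 4032x128 + 128x64 + 64x32 + 32x1 with biases
  expect_identical(octfocus:::nn_n_params(actor),
                   400L + 1568L + (4032L * 128L + 128L) +
                     (128L * 64L + 64L) + (64L * 32L + 32L) + (32L + 1L))
  # batch evaluation equals stacked per-sample evaluation
  obs_b <- array(rnorm(3 * 8 * 512), dim = c(3, 8, 512))
  batch <- octfocus:::actor_forward(actor, obs_b)
  for (i in 1:3)
    expect_equal(batch[i],
                 octfocus:::actor_forward(actor,
                                          matrix(obs_b[i, , ], 8, 512)))
})

test_that("critic consumes the action (nonzero finite-difference gradient)", {
  set.seed(6)
  critic <- octfocus:::build_critic(8L, 384L)
  obs <- matrix(rnorm(8 * 384), 8, 384)
  q0 <- octfocus:::critic_forward(critic, obs, 0.2)
  expect_length(q0, 1)
  expect_true(is.finite(q0))
  h <- 1e-4
  grad_fd <- (octfocus:::critic_forward(critic, obs, 0.2 + h) -
                octfocus:::critic_forward(critic, obs, 0.2 - h)) / (2 * h)
  expect_gt(abs(grad_fd), 1e-8)
  # analytic action gradient agrees with the finite difference
  fb <- octfocus:::critic_forward_backward(
    critic, octfocus:::as_obs_batch(obs), 0.2, function(q) 1)
  expect_equal(fb$d_action, grad_fd, tolerance = 1e-4)
})

test_that("exploration returns the requested transitions under the noise schedule", {
  p <- test_params()
  ph <- test_phantom()
  cfg <- agent_config(train_steps = 100L)
  set.seed(7)
  ep <- sim_episode(ph, p, cfg)
  actor <- octfocus:::build_actor(8L, p$n_depth_pixels)
  # zero noise, one profile: the pure actor action
  tr <- explore_step(ep, actor, noise_sigma = 0, n_noise_profiles = 1)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$action, octfocus:::actor_forward(actor, ep$obs))
  expect_lte(tr[[1]]$reward, 0)
  # five profiles share the observation
  tr5 <- explore_step(ep, actor, noise_sigma = 0.3, n_noise_profiles = 5)
  expect_length(tr5, 5)
  for (t in tr5) expect_identical(t$obs, ep$obs)
  expect_true(all(vapply(tr5, function(t) abs(t$action) < 1, logical(1))))
  # linear annealing schedule endpoints
  expect_equal(octfocus:::noise_sigma_at(cfg, 1), cfg$noise_sigma_start)
  expect_equal(octfocus:::noise_sigma_at(cfg, 80), cfg$noise_sigma_end)
  expect_equal(octfocus:::noise_sigma_at(cfg, 100), cfg$noise_sigma_end)
  mid <- octfocus:::noise_sigma_at(cfg, 40)
  expect_lt(mid, cfg$noise_sigma_start)
  expect_gt(mid, cfg$noise_sigma_end)
})

test_that("the reward peaks when the correction cancels the applied defocus", {
  p <- test_params()
  ph <- test_phantom()
  cfg <- agent_config()
  set.seed(8)
  ep <- sim_episode(ph, p, cfg)
  d <- ep$applied_defocus
  r_true <- ep$apply_correction(d)
  r_off <- vapply(c(-0.4, 0.3, 0.5), function(off) ep$apply_correction(d + off),
                  numeric(1))
  expect_true(all(r_true > r_off))
})

test_that("critic regression on a frozen buffer reduces its loss", {
  p <- test_params()
  ph <- test_phantom()
  cfg <- agent_config(batch_size = 32L, critic_lr = 1e-3)
  set.seed(9)
  # frozen synthetic buffer: rewards follow a simple function of defocus
  buf <- octfocus:::buffer_new(64L, 8L, p$n_depth_pixels)
  actor <- octfocus:::build_actor(8L, p$n_depth_pixels)
  for (i in 1:16) {
    ep <- sim_episode(ph, p, cfg)
    octfocus:::buffer_add(buf, explore_step(ep, actor, 0.3, 4))
  }
  critic <- octfocus:::build_critic(8L, p$n_depth_pixels)
  state <- list(cfg = cfg, actor = actor, critic = critic,
                actor_target = octfocus:::nn_deep_copy(actor),
                critic_target = octfocus:::critic_deep_copy(critic),
                adam_actor = octfocus:::nn_adam_state(actor),
                adam_critic_trunk = octfocus:::nn_adam_state(critic$trunk),
                adam_critic_head = octfocus:::nn_adam_state(critic$head))
  losses <- numeric(30)
  for (u in 1:30) {
    batch <- octfocus:::buffer_sample(buf, cfg$batch_size)
    state <- octfocus:::ddpg_update(state, batch)
    losses[u] <- state$critic_loss
  }
  expect_lt(mean(losses[21:30]), mean(losses[1:10]))
  expect_true(all(is.finite(losses)))
})
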