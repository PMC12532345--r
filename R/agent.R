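#' Configuration for the focus-correction DDPG agent
#'
#' Hyperparameters of the single-step DDPG agent and of the simulated
#' training protocol. Episodes are single-step: the critic regresses the
#' immediate reward (no bootstrapping), and the actor ascends the critic.
#'
#' @param action_scale Physical correction per unit action, D (the tanh
#'   output in (-1,1) maps to +/- `action_scale` diopters).
#' @param Nb Sliding-window half-range of the reward, pixels.
#' @param M Number of lateral sub-regions per B-scan (observation has 2M
#'   channels).
#' @param smoothing_sigma Gaussian sd for channel smoothing, pixels.
#' @param noise_sigma_start,noise_sigma_end Exploration noise sd (action
#'   units) at the start and end of the linear annealing schedule.
#' @param noise_anneal_frac Fraction of training steps over which the noise
#'   anneals linearly (constant at `noise_sigma_end` afterwards).
#' @param n_noise_profiles Number of perturbed actions (and rewards) per
#'   episode stored in the replay buffer.
#' @param buffer_capacity Replay buffer capacity (transitions).
#' @param batch_size Minibatch size.
#' @param actor_lr,critic_lr Adam learning rates.
#' @param soft_update_tau Polyak factor for the target networks.
#' @param train_steps Number of training episodes.
#' @param updates_per_step Gradient updates per environment step.
#' @param policy_delay Actor update period in critic updates (TD3-style
#'   delayed policy updates; 1 = update both every step).
#' @param critic_pretrain_steps Critic-only regression updates run on the
#'   warmup buffer before joint training starts, so the actor ascends an
#'   informative landscape from its first update.
#' @param warmup_steps Episodes collected with uniform random actions
#'   before updates begin.
#' @param defocus_range Training defocus range, D (uniform).
#' @param motion_range_um Training target axial-motion range, um (uniform).
#' @param reference_variation_D Total range of the random reference focus, D
#'   (uniform about the mid-retina focus).
#' @param initial_motion_range_um Total range of the random initial retina
#'   placement shared by reference and target, um.
#' @param eval_episodes Held-out episodes for the final evaluation.
#' @param eval_every Learning-curve evaluation period (steps).
#' @param eval_curve_episodes Episodes per learning-curve point.
#' @param rng_seed Integer seed for all training randomness.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(action_scale = 1.0,
                         Nb = 15L,
                         M = 4L,
                         smoothing_sigma = 2,
                         noise_sigma_start = 0.3,
                         noise_sigma_end = 0.02,
                         noise_anneal_frac = 0.8,
                         n_noise_profiles = 6L,
                         buffer_capacity = 50000L,
                         batch_size = 32L,
                         actor_lr = 3e-4,
                         critic_lr = 1e-3,
                         soft_update_tau = 0.005,
                         train_steps = 3000L,
                         updates_per_step = 1L,
                         policy_delay = 2L,
                         critic_pretrain_steps = 300L,
                         warmup_steps = 60L,
                         defocus_range = c(-0.6, 0.6),
                         motion_range_um = c(-200, 200),
                         reference_variation_D = 0.5,
                         initial_motion_range_um = 200,
                         eval_episodes = 100L,
                         eval_every = 250L,
                         eval_curve_episodes = 20L,
                         rng_seed = 1L) {
  cfg <- list(action_scale = action_scale, Nb = as.integer(Nb),
              M = as.integer(M), smoothing_sigma = smoothing_sigma,
              noise_sigma_start = noise_sigma_start,
              noise_sigma_end = noise_sigma_end,
              noise_anneal_frac = noise_anneal_frac,
              n_noise_profiles = as.integer(n_noise_profiles),
              buffer_capacity = as.integer(buffer_capacity),
              batch_size = as.integer(batch_size),
              actor_lr = actor_lr, critic_lr = critic_lr,
              soft_update_tau = soft_update_tau,
              train_steps = as.integer(train_steps),
              updates_per_step = as.integer(updates_per_step),
              policy_delay = as.integer(policy_delay),
              critic_pretrain_steps = as.integer(critic_pretrain_steps),
              warmup_steps = as.integer(warmup_steps),
              defocus_range = defocus_range,
              motion_range_um = motion_range_um,
              reference_variation_D = reference_variation_D,
              initial_motion_range_um = initial_motion_range_um,
              eval_episodes = as.integer(eval_episodes),
              eval_every = as.integer(eval_every),
              eval_curve_episodes = as.integer(eval_curve_episodes),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$action_scale > 0, cfg$Nb >= 0, cfg$M >= 1,
            cfg$n_noise_profiles >= 1, cfg$train_steps >= 1)
  class(cfg) <- "agent_config"
  cfg
}

#' Sliding-window focus reward
#'
#' Reward for the focus-correction agent: the negative of the minimum
#' Euclidean distance between the jointly normalized reference and target
#' averaged A-scans, minimized over integer axial shifts `b` in
#' `[-Nb, Nb]` of the target. The sliding window forgives residual axial
#' motion up to `Nb` pixels, so the reward reflects focus similarity rather
#' than registration accuracy. Always <= 0; 0 iff some shift makes the
#' normalized profiles identical.
#'
#' @param a_ref,a_tgt Averaged A-scans (equal length, non-constant jointly).
#' @param Nb Sliding half-range, pixels (>= 0).
#' @return Scalar reward `R_f <= 0`.
#' @export
reward_focus <- function(a_ref, a_tgt, Nb = 15) {
  np <- normalize_pair(a_ref, a_tgt)
  n <- length(a_ref)
  Nb <- as.integer(Nb)
  stopifnot(Nb >= 0, Nb < n)
  if (Nb == 0) return(ed_metric(np$ref_norm, np$tgt_norm))
  max(ed_shift_curve(np$ref_norm, np$tgt_norm, Nb))
}

# mid-retina reference focal depth for a phantom, um
phantom_mid_zf <- function(phantom, params) {
  inner <- if (is.na(phantom$inner_band_center)) phantom$outer_band_center
           else phantom$inner_band_center
  ((inner + phantom$outer_band_center) / 2 - 1) * params$axial_pixel_pitch
}

#' Simulated single-step correction episode
#'
#' Draws one training/evaluation episode from the simulated protocol:
#' a reference frame with randomized initial retina placement and reference
#' focus, and a target frame with uniform random defocus and axial motion.
#' The target is motion-corrected against the reference with the masked-EDM
#' registration, and the 2M-channel observation is built from both frames.
#'
#' The returned environment exposes `apply_correction(diopters)`, which
#' re-renders the target with the lens moved by the predicted correction,
#' applies the same motion correction, and returns the sliding-window
#' reward against the reference.
#'
#' Uses the current global RNG stream (seed at the call site).
#'
#' @param phantom A [make_phantom()] object.
#' @param params An [oct_params()] object.
#' @param cfg An [agent_config()] object.
#' @return List with `obs` (2M x depth), `applied_defocus` (D), registration
#'   info, and the `apply_correction` closure.
#' @export
sim_episode <- function(phantom, params, cfg) {
  half_init <- cfg$initial_motion_range_um / 2
  half_ref <- cfg$reference_variation_D / 2
  shift_ref <- stats::runif(1, -half_init, half_init)
  zf_ref <- phantom_mid_zf(phantom, params) +
    stats::runif(1, -half_ref, half_ref) * params$diopter_to_depth
  d_applied <- stats::runif(1, cfg$defocus_range[1], cfg$defocus_range[2])
  shift_tgt <- shift_ref +
    stats::runif(1, cfg$motion_range_um[1], cfg$motion_range_um[2])
  st_ref <- focus_state(zf_ref, 0, shift_ref, params)
  st_tgt <- focus_state(zf_ref, d_applied, shift_tgt, params)
  ref <- render_bscan(phantom, st_ref, params)
  tgt <- render_bscan(phantom, st_tgt, params)
  reg <- register_axial(ref, tgt, params = params)
  tgt_corr <- apply_axial_correction(tgt, reg$shift_pixels)
  ref_ch <- subregion_channels(ref, cfg$M, cfg$smoothing_sigma)
  tgt_ch <- subregion_channels(tgt_corr, cfg$M, cfg$smoothing_sigma)
  obs <- build_observation(ref_ch, tgt_ch)
  a_ref_avg <- average_ascan(ref)
  apply_correction <- function(predicted_D) {
    st_new <- focus_state(zf_ref, d_applied - predicted_D, shift_tgt, params)
    new_tgt <- render_bscan(phantom, st_new, params)
    new_corr <- apply_axial_correction(new_tgt, reg$shift_pixels)
    reward_focus(a_ref_avg, average_ascan(new_corr), cfg$Nb)
  }
  list(obs = obs, applied_defocus = d_applied,
       registration = reg, ref = ref, tgt = tgt_corr,
       apply_correction = apply_correction)
}

#' One exploration step of the single-step DDPG agent
#'
#' Computes the actor action for the episode's observation, perturbs it with
#' `n_noise_profiles` independent Gaussian noise draws (sd `noise_sigma`,
#' clipped to (-1, 1)), applies each perturbed correction in the simulated
#' environment, and returns one transition per noise profile. Because
#' episodes are single-step with immediate reward, several rewards can be
#' harvested from one observation, enhancing exploration.
#'
#' @param env An episode from [sim_episode()].
#' @param actor The actor network.
#' @param noise_sigma Exploration noise sd in action units.
#' @param n_noise_profiles Number of perturbed actions.
#' @param action_scale Diopters per unit action.
#' @return List of transitions, each `list(obs, action, reward)`.
#' @export
explore_step <- function(env, actor, noise_sigma, n_noise_profiles = 1L,
                         action_scale = 1.0) {
  a0 <- actor_forward(actor, env$obs)
  lapply(seq_len(n_noise_profiles), function(i) {
    a <- a0 + if (noise_sigma > 0) stats::rnorm(1, 0, noise_sigma) else 0
    a <- min(max(a, -0.999), 0.999)
    list(obs = env$obs, action = a,
         reward = env$apply_correction(a * action_scale))
  })
}

# exploration noise sd at step t (linear annealing)
noise_sigma_at <- function(cfg, t) {
  t_anneal <- max(1, round(cfg$noise_anneal_frac * cfg$train_steps))
  if (t >= t_anneal) return(cfg$noise_sigma_end)
  cfg$noise_sigma_start +
    (cfg$noise_sigma_end - cfg$noise_sigma_start) * (t - 1) / (t_anneal - 1)
}

# ring replay buffer: observations live as flattened columns of one large
# matrix, written and gathered through C so the store is never duplicated
buffer_new <- function(capacity, n_channels, depth) {
  env <- new.env(parent = emptyenv())
  env$obs_flat <- matrix(0, nrow = n_channels * depth, ncol = capacity)
  env$n_channels <- as.integer(n_channels)
  env$depth <- as.integer(depth)
  env$action <- numeric(capacity)
  env$reward <- numeric(capacity)
  env$capacity <- as.integer(capacity)
  env$n <- 0L
  env$pos <- 0L
  env
}

buffer_add <- function(buf, transitions) {
  for (tr in transitions) {
    buf$pos <- (buf$pos %% buf$capacity) + 1L
    .Call(C_buf_write, buf$obs_flat, buf$pos, as.numeric(tr$obs))
    buf$action[buf$pos] <- tr$action
    buf$reward[buf$pos] <- tr$reward
    buf$n <- min(buf$n + 1L, buf$capacity)
  }
  invisible(buf)
}

buffer_sample <- function(buf, batch_size) {
  idx <- sample.int(buf$n, batch_size, replace = buf$n < batch_size)
  list(obs = .Call(C_buf_gather, buf$obs_flat, as.integer(idx),
                   c(buf$n_channels, buf$depth)),
       action = buf$action[idx], reward = buf$reward[idx])
}

# one critic regression step (target = immediate reward) and one actor
# ascent step through the critic, plus polyak target updates
ddpg_update <- function(state, batch) {
  cfg <- state$cfg
  b <- length(batch$action)
  lr_scale <- state$lr_scale %||% 1
  critic_lr <- cfg$critic_lr * lr_scale
  actor_lr <- cfg$actor_lr * lr_scale
  # critic: MSE regression to the immediate reward
  resid <- NULL
  fb <- critic_forward_backward(state$critic, batch$obs, batch$action,
                                dloss_fn = function(q) {
                                  resid <<- q - batch$reward
                                  2 * resid / b
                                })
  up <- nn_adam_step(state$critic$trunk, fb$grads_trunk,
                     state$adam_critic_trunk, critic_lr)
  state$critic$trunk <- up$net; state$adam_critic_trunk <- up$state
  up <- nn_adam_step(state$critic$head, fb$grads_head,
                     state$adam_critic_head, critic_lr)
  state$critic$head <- up$net; state$adam_critic_head <- up$state
  state$critic_loss <- mean(resid^2)
  state$n_updates <- (state$n_updates %||% 0L) + 1L
  # actor (every policy_delay-th update): ascend Q(s, pi(s)); only the
  # action gradient is needed from the critic, so its parameter-gradient
  # GEMMs and the trunk backward pass are skipped
  if (state$n_updates %% (cfg$policy_delay %||% 1L) == 0L) {
    fw_a <- nn_forward(state$actor, batch$obs, keep_cache = TRUE)
    a_pi <- as.numeric(fw_a$out)
    fb2 <- critic_forward_backward(state$critic, batch$obs, a_pi,
                                   dloss_fn = function(q) rep(-1 / b, b),
                                   param_grads = FALSE,
                                   trunk_backward = FALSE)
    bw_a <- nn_backward(state$actor, fw_a$caches,
                        matrix(fb2$d_action, ncol = 1))
    up <- nn_adam_step(state$actor, bw_a$grads, state$adam_actor,
                       actor_lr)
    state$actor <- up$net; state$adam_actor <- up$state
    if (!all(is.finite(a_pi)))
      stop("training diverged: non-finite actor output")
  }
  if (!is.finite(state$critic_loss))
    stop("training diverged: non-finite critic loss")
  # target networks (polyak); with single-step returns the critic target is
  # the immediate reward, so these stabilize only the actor's landscape
  state$actor_target <- nn_soft_update(state$actor_target, state$actor,
                                       cfg$soft_update_tau)
  state$critic_target$trunk <- nn_soft_update(state$critic_target$trunk,
                                              state$critic$trunk,
                                              cfg$soft_update_tau)
  state$critic_target$head <- nn_soft_update(state$critic_target$head,
                                             state$critic$head,
                                             cfg$soft_update_tau)
  state
}

# greedy evaluation on fresh episodes (uses current RNG stream)
eval_policy <- function(actor, phantom, params, cfg, n_episodes) {
  errs <- numeric(n_episodes)
  rews <- numeric(n_episodes)
  for (i in seq_len(n_episodes)) {
    ep <- sim_episode(phantom, params, cfg)
    a <- actor_forward(actor, ep$obs)
    pred <- a * cfg$action_scale
    errs[i] <- abs(pred - ep$applied_defocus)
    rews[i] <- ep$apply_correction(pred)
  }
  list(mean_abs_error = mean(errs), mean_reward = mean(rews), errors = errs)
}

#' Train the single-step DDPG focus-correction agent
#'
#' Trains the actor-critic agent in the simulated environment: per episode a
#' reference/target pair is rendered with random defocus and axial motion,
#' the motion is corrected first by masked-EDM registration, the 2M-channel
#' observation is built, and the actor's (noise-perturbed) corrections are
#' applied in simulation to harvest immediate sliding-window rewards.
#' Because episodes are single-step, the critic regresses the immediate
#' reward directly and the actor ascends the critic.
#'
#' @param phantom A [make_phantom()] object (the retina being imaged).
#' @param params An [oct_params()] object.
#' @param config An [agent_config()] object.
#' @param verbose Print learning-curve progress.
#' @return An object of class `focus_agent` with the trained networks, the
#'   configuration, the learning-curve data frame (`curve`), and the final
#'   held-out evaluation (`final_eval`).
#' @seealso [predict.focus_agent()], [evaluate_agent()], [run_session()]
#' @export
train_focus_agent <- function(phantom = make_phantom(),
                              params = oct_params(),
                              config = agent_config(),
                              verbose = interactive()) {
  cfg <- config
  set.seed(cfg$rng_seed)
  n_ch <- 2L * cfg$M
  depth <- params$n_depth_pixels
  actor <- build_actor(n_ch, depth)
  critic <- build_critic(n_ch, depth)
  state <- list(
    cfg = cfg, actor = actor, critic = critic,
    actor_target = nn_deep_copy(actor),
    critic_target = critic_deep_copy(critic),
    adam_actor = nn_adam_state(actor),
    adam_critic_trunk = nn_adam_state(critic$trunk),
    adam_critic_head = nn_adam_state(critic$head)
  )
  cap <- min(cfg$buffer_capacity,
             cfg$train_steps * cfg$n_noise_profiles + cfg$n_noise_profiles)
  buf <- buffer_new(cap, n_ch, depth)
  curve <- list()
  for (t in seq_len(cfg$train_steps)) {
    ep <- sim_episode(phantom, params, cfg)
    sigma <- noise_sigma_at(cfg, t)
    if (t <= cfg$warmup_steps) {
      # uniform random actions during warmup: the critic sees the whole
      # action range before the actor starts following its gradient
      trans <- lapply(seq_len(cfg$n_noise_profiles), function(i) {
        a <- stats::runif(1, -0.999, 0.999)
        list(obs = ep$obs, action = a,
             reward = ep$apply_correction(a * cfg$action_scale))
      })
    } else {
      trans <- explore_step(ep, state$actor, sigma, cfg$n_noise_profiles,
                            cfg$action_scale)
    }
    buffer_add(buf, trans)
    if (t == cfg$warmup_steps && cfg$critic_pretrain_steps > 0) {
      # critic-only regression on the uniform-action warmup buffer
      delay <- state$cfg$policy_delay
      state$cfg$policy_delay <- .Machine$integer.max
      for (u in seq_len(cfg$critic_pretrain_steps)) {
        state <- ddpg_update(state, buffer_sample(buf, cfg$batch_size))
      }
      state$cfg$policy_delay <- delay
      state$n_updates <- 0L
    }
    if (t > cfg$warmup_steps && buf$n >= cfg$batch_size) {
      # linear learning-rate decay to 20% over the run steadies the
      # end-of-training policy
      state$lr_scale <- 1 - 0.8 * (t - 1) / cfg$train_steps
      for (u in seq_len(cfg$updates_per_step)) {
        batch <- buffer_sample(buf, cfg$batch_size)
        state <- ddpg_update(state, batch)
      }
    }
    if (t %% cfg$eval_every == 0 || t == cfg$train_steps) {
      ev <- eval_policy(state$actor, phantom, params, cfg,
                        cfg$eval_curve_episodes)
      curve[[length(curve) + 1]] <- data.frame(
        step = t, mean_abs_error_D = ev$mean_abs_error,
        mean_reward = ev$mean_reward,
        critic_loss = state$critic_loss %||% NA_real_,
        noise_sigma = sigma)
      if (verbose)
        message(sprintf("step %4d | err %.4f D | reward %.4f | closs %.4g",
                        t, ev$mean_abs_error, ev$mean_reward,
                        state$critic_loss %||% NA))
    }
  }
  final_eval <- eval_policy(state$actor, phantom, params, cfg,
                            cfg$eval_episodes)
  structure(list(actor = state$actor, critic = state$critic,
                 actor_target = state$actor_target,
                 critic_target = state$critic_target,
                 config = cfg, phantom = phantom, params = params,
                 curve = do.call(rbind, curve),
                 final_eval = final_eval),
            class = "focus_agent")
}

#' Evaluate a trained agent on held-out episodes
#'
#' Draws fresh episodes from the training protocol and reports the mean
#' absolute difference between the predicted and the applied defocus.
#'
#' @param agent A `focus_agent`.
#' @param n_episodes Number of evaluation episodes.
#' @param rng_seed Optional integer seed.
#' @param phantom Optional phantom to evaluate on (defaults to the
#'   training phantom).
#' @return List with `mean_abs_error` (D), `mean_reward` and the per-episode
#'   `errors`.
#' @export
evaluate_agent <- function(agent, n_episodes = 100, rng_seed = NULL,
                           phantom = NULL) {
  stopifnot(inherits(agent, "focus_agent"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  eval_policy(agent$actor, phantom %||% agent$phantom, agent$params,
              agent$config, n_episodes)
}

#' Predict the defocus correction for a frame pair
#'
#' Runs the inference path of the correction pipeline: optionally registers
#' the target to the reference axially, builds the 2M-channel observation,
#' and maps it through the actor. The return value is the predicted applied
#' defocus in diopters; the lens correction to command is its negative.
#'
#' @param object A trained `focus_agent`.
#' @param ref_bscan,tgt_bscan `bscan` objects (or depth x lateral matrices).
#' @param register If `TRUE` (default), motion-correct the target first.
#' @param ... Unused.
#' @return Predicted defocus, diopters.
#' @export
predict.focus_agent <- function(object, ref_bscan, tgt_bscan,
                                register = TRUE, ...) {
  cfg <- object$config
  if (register) {
    reg <- register_axial(ref_bscan, tgt_bscan, params = object$params)
    tgt_bscan <- apply_axial_correction(tgt_bscan, reg$shift_pixels)
  }
  ref_ch <- subregion_channels(ref_bscan, cfg$M, cfg$smoothing_sigma)
  tgt_ch <- subregion_channels(tgt_bscan, cfg$M, cfg$smoothing_sigma)
  obs <- build_observation(ref_ch, tgt_ch)
  actor_forward(object$actor, obs) * cfg$action_scale
}

#' @export
print.focus_agent <- function(x, ...) {
  cat("Single-step DDPG focus-correction agent\n")
  cat(sprintf("  observation: %d channels x %d depth px (M = %d)\n",
              2 * x$config$M, x$params$n_depth_pixels, x$config$M))
  cat(sprintf("  actor parameters: %s | critic parameters: %s\n",
              format(nn_n_params(x$actor), big.mark = ","),
              format(nn_n_params(x$critic$trunk) + nn_n_params(x$critic$head),
                     big.mark = ",")))
  cat(sprintf("  trained %d steps; held-out mean |focus error| = %.4f D\n",
              x$config$train_steps, x$final_eval$mean_abs_error))
  invisible(x)
}

#' @export
summary.focus_agent <- function(object, ...) {
  cat("Single-step DDPG focus-correction agent\n\n")
  cat("Training configuration:\n")
  cfg <- object$config
  cat(sprintf("  steps %d, noise %.2f -> %.2f over %.0f%%, %d noise profiles/step\n",
              cfg$train_steps, cfg$noise_sigma_start, cfg$noise_sigma_end,
              100 * cfg$noise_anneal_frac, cfg$n_noise_profiles))
  cat(sprintf("  defocus U(%.1f, %.1f) D, motion U(%.0f, %.0f) um, reference +/- %.2f D\n",
              cfg$defocus_range[1], cfg$defocus_range[2],
              cfg$motion_range_um[1], cfg$motion_range_um[2],
              cfg$reference_variation_D / 2))
  cat(sprintf("  lr actor %.1e / critic %.1e, batch %d, tau %.3f\n\n",
              cfg$actor_lr, cfg$critic_lr, cfg$batch_size,
              cfg$soft_update_tau))
  ev <- object$final_eval
  cat(sprintf("Held-out evaluation (%d episodes):\n", length(ev$errors)))
  cat(sprintf("  mean |focus error| %.4f D (sd %.4f), mean reward %.4f\n",
              ev$mean_abs_error, stats::sd(ev$errors), ev$mean_reward))
  invisible(object)
}

#' @export
plot.focus_agent <- function(x, ...) {
  graphics::plot(x$curve$step, x$curve$mean_abs_error_D, type = "b",
                 log = "y", xlab = "training step",
                 ylab = "mean |focus error| (D)",
                 main = "Focus-correction learning curve", ...)
  invisible(x)
}
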