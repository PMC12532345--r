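#' Simulator-backed focus sweep source
#'
#' Returns a function `f(focus_D)` that renders a B-scan of `phantom` at
#' defocus `focus_D` relative to the mid-retina reference focus, with
#' optional per-frame random axial motion — a stand-in for swept-focus
#' hardware acquisition.
#'
#' @param phantom A [make_phantom()] object.
#' @param params An [oct_params()] object.
#' @param motion_sd_um Per-frame random axial motion sd, um.
#' @param reference_defocus_D Reference focus offset from mid-retina, D.
#' @return A function of one argument (defocus, D) returning a `bscan`.
#' @export
sweep_source_simulator <- function(phantom, params = oct_params(),
                                   motion_sd_um = 0,
                                   reference_defocus_D = 0) {
  zf_ref <- phantom_mid_zf(phantom, params) +
    reference_defocus_D * params$diopter_to_depth
  function(focus_D) {
    shift <- if (motion_sd_um > 0) stats::rnorm(1, 0, motion_sd_um) else 0
    render_bscan(phantom, focus_state(zf_ref, focus_D, shift, params), params)
  }
}

#' Acquire a sparse focus sweep
#'
#' Acquires one B-scan per requested focus value from `source`, registers
#' each frame axially to the central frame of the sweep (masked-EDM
#' pixel-shift registration; the central frame sees the most balanced band
#' illumination, which symmetrizes the small defocus-dependent apparent
#' shift of band edges), and reduces each to M smoothed sub-region A-scan
#' channels. The sweep is the raw material for the interpolated focus map
#' used in fast fine-tuning; a full sweep needs exactly
#' `length(focus_values)` frames.
#'
#' @param source A function `f(focus_D) -> bscan` (e.g.
#'   [sweep_source_simulator()]).
#' @param focus_values Strictly increasing defocus values, D.
#' @param params An [oct_params()] object.
#' @param M Sub-region count.
#' @param smoothing_sigma Channel smoothing sd, pixels.
#' @param register Register frames to the central frame before reduction.
#' @param n_frames_per_focus Frames averaged per focus value (batch
#'   acquisition suppresses the per-frame noise floor and gain jitter of
#'   the sweep samples).
#' @return An object of class `focus_sweep`: `focus_values`, `channels`
#'   (`n_focus x M x depth` array), `shifts_px`, `M`, `smoothing_sigma`,
#'   `registered`.
#' @export
acquire_sweep <- function(source, focus_values, params = oct_params(),
                          M = 4, smoothing_sigma = 2, register = TRUE,
                          n_frames_per_focus = 1L) {
  stopifnot(length(focus_values) >= 2, all(diff(focus_values) > 0),
            n_frames_per_focus >= 1)
  n_f <- length(focus_values)
  depth <- params$n_depth_pixels
  ch <- array(0, dim = c(n_f, M, depth))
  shifts <- integer(n_f)
  frames <- lapply(focus_values, function(f) {
    fr <- source(f)
    if (n_frames_per_focus > 1L) {
      img <- if (inherits(fr, "bscan")) fr$intensity else fr
      for (j in seq_len(n_frames_per_focus - 1L)) {
        nxt <- source(f)
        img <- img + if (inherits(nxt, "bscan")) nxt$intensity else nxt
      }
      img <- img / n_frames_per_focus
      if (inherits(fr, "bscan")) fr$intensity <- img else fr <- img
    }
    fr
  })
  i_ref <- (n_f + 1L) %/% 2L
  for (i in seq_len(n_f)) {
    fr <- frames[[i]]
    if (register && i != i_ref) {
      reg <- register_axial(frames[[i_ref]], fr, params = params)
      shifts[i] <- reg$shift_pixels
      fr <- apply_axial_correction(fr, reg$shift_pixels)
    }
    ch[i, , ] <- subregion_channels(fr, M, smoothing_sigma)$channels
  }
  structure(list(focus_values = focus_values, channels = ch,
                 shifts_px = shifts, M = M,
                 smoothing_sigma = smoothing_sigma, registered = register),
            class = "focus_sweep")
}

#' Build a dense A-scan focus map from a sparse sweep
#'
#' For each depth pixel and channel, interpolates the A-scan intensity along
#' the focus axis (linear by default, monotone-safe; `"cubic"` uses natural
#' splines). The interpolation passes exactly through the sweep samples.
#'
#' @param sweep A [acquire_sweep()] result.
#' @param dense_step Dense grid step, D.
#' @param method `"linear"` or `"cubic"`.
#' @return An object of class `focus_map` with `dense_focus_grid`,
#'   `interpolated_channels` (`n_dense x M x depth`), the originating
#'   `sweep` and the interpolation `method`.
#' @export
build_focus_map <- function(sweep, dense_step = 0.01,
                            method = c("linear", "cubic")) {
  method <- match.arg(method)
  stopifnot(inherits(sweep, "focus_sweep"), length(sweep$focus_values) >= 2)
  fv <- sweep$focus_values
  grid <- seq(fv[1], fv[length(fv)], by = dense_step)
  dims <- dim(sweep$channels)
  dense <- array(0, dim = c(length(grid), dims[2], dims[3]))
  for (m in seq_len(dims[2])) {
    for (z in seq_len(dims[3])) {
      y <- sweep$channels[, m, z]
      dense[, m, z] <- if (method == "linear") {
        stats::approx(fv, y, xout = grid)$y
      } else {
        stats::spline(fv, y, xout = grid, method = "natural")$y
      }
    }
  }
  structure(list(dense_focus_grid = grid, interpolated_channels = dense,
                 sweep = sweep, method = method,
                 focus_range = range(fv)),
            class = "focus_map")
}

#' Interpolated channels at an arbitrary focus value
#'
#' Looks up the `M x depth` channel set at focus `f` by interpolating the
#' sweep knots directly (exact at knots). Queries outside the sweep range
#' are rejected.
#'
#' @param map A [build_focus_map()] result.
#' @param f Focus value, D.
#' @return An `M x depth` matrix.
#' @export
focus_map_channels <- function(map, f) {
  stopifnot(inherits(map, "focus_map"))
  fv <- map$sweep$focus_values
  if (f < fv[1] - 1e-12 || f > fv[length(fv)] + 1e-12)
    stop(sprintf("focus %.3f D outside the sweep range [%.2f, %.2f] D",
                 f, fv[1], fv[length(fv)]))
  f <- min(max(f, fv[1]), fv[length(fv)])
  hit <- which(abs(fv - f) < 1e-12)
  if (length(hit)) return(map$sweep$channels[hit[1], , ])
  i <- findInterval(f, fv)
  if (map$method == "linear") {
    w <- (f - fv[i]) / (fv[i + 1] - fv[i])
    (1 - w) * map$sweep$channels[i, , ] + w * map$sweep$channels[i + 1, , ]
  } else {
    dims <- dim(map$sweep$channels)
    out <- matrix(0, dims[2], dims[3])
    for (m in seq_len(dims[2]))
      for (z in seq_len(dims[3]))
        out[m, z] <- stats::spline(fv, map$sweep$channels[, m, z],
                                   xout = f, method = "natural")$y
    out
  }
}

# single-step episode served by focus-map lookups instead of fresh renders;
# the (reference focus, defocus) distribution mirrors the simulator training
# protocol so fine-tuning does not drag the policy off the evaluation
# distribution
map_episode <- function(map, cfg) {
  fr <- map$focus_range
  d_lo <- max(cfg$defocus_range[1], fr[1] - fr[2])
  d_hi <- min(cfg$defocus_range[2], fr[2] - fr[1])
  d <- stats::runif(1, d_lo, d_hi)
  half_ref <- cfg$reference_variation_D / 2
  f_ref <- stats::runif(1,
                        max(-half_ref, fr[1], fr[1] - min(d, 0)),
                        min(half_ref, fr[2], fr[2] - max(d, 0)))
  ref_ch <- structure(list(channels = focus_map_channels(map, f_ref),
                           M = cfg$M, smoothing_sigma = cfg$smoothing_sigma),
                      class = "ascan_channels")
  roll <- sample.int(5L, 1L) - 3L   # residual motion the window must forgive
  tgt_mat <- roll_rows(focus_map_channels(map, f_ref + d), roll)
  tgt_ch <- structure(list(channels = tgt_mat, M = cfg$M,
                           smoothing_sigma = cfg$smoothing_sigma),
                      class = "ascan_channels")
  obs <- build_observation(ref_ch, tgt_ch)
  a_ref <- colMeans(ref_ch$channels)
  apply_correction <- function(predicted_D) {
    f_new <- min(max(f_ref + d - predicted_D, fr[1]), fr[2])
    new_ch <- roll_rows(focus_map_channels(map, f_new), roll)
    reward_focus(a_ref, colMeans(new_ch), cfg$Nb)
  }
  list(obs = obs, applied_defocus = d, apply_correction = apply_correction)
}

# roll matrix columns (depth axis of an M x depth channel matrix)
roll_rows <- function(ch, k) {
  if (k == 0) return(ch)
  n <- ncol(ch)
  idx <- ((seq_len(n) - 1 - k) %% n) + 1
  ch[, idx, drop = FALSE]
}

#' Fine-tune a trained agent on an interpolated focus map
#'
#' Runs the same single-step DDPG loop as [train_focus_agent()], but the
#' environment's `apply_correction` is served by [focus_map_channels()]
#' lookups instead of fresh renders — emulating fast fine-tuning on sparsely
#' acquired focus-swept data of a new retinal structure. With `steps = 0`
#' the agent is returned unchanged.
#'
#' @param agent A trained `focus_agent`.
#' @param focus_map A [build_focus_map()] result.
#' @param steps Number of fine-tuning episodes/updates.
#' @param noise_sigma Exploration noise sd (action units), constant during
#'   fine-tuning.
#' @param rng_seed Integer seed.
#' @param verbose Print progress.
#' @return The fine-tuned `focus_agent` (with `finetune_curve` attached).
#' @export
finetune_agent <- function(agent, focus_map, steps = 2000,
                           noise_sigma = 0.05, rng_seed = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(agent, "focus_agent"), inherits(focus_map, "focus_map"))
  if (steps == 0) return(agent)
  cfg <- agent$config
  set.seed(rng_seed)
  # deep-copy so in-place optimizer steps cannot touch the caller's agent
  state <- list(cfg = cfg, actor = nn_deep_copy(agent$actor),
                critic = critic_deep_copy(agent$critic),
                actor_target = nn_deep_copy(agent$actor_target),
                critic_target = critic_deep_copy(agent$critic_target),
                adam_actor = nn_adam_state(agent$actor),
                adam_critic_trunk = nn_adam_state(agent$critic$trunk),
                adam_critic_head = nn_adam_state(agent$critic$head),
                # continue at the end-of-training decayed learning rate:
                # full-rate updates with fresh Adam moments would wreck a
                # converged policy before the new data can refine it
                lr_scale = 0.2)
  depth <- agent$params$n_depth_pixels
  buf <- buffer_new(min(cfg$buffer_capacity,
                        steps * cfg$n_noise_profiles + cfg$n_noise_profiles),
                    2L * cfg$M, depth)
  curve <- list()
  for (t in seq_len(steps)) {
    ep <- map_episode(focus_map, cfg)
    trans <- explore_step(ep, state$actor, noise_sigma,
                          cfg$n_noise_profiles, cfg$action_scale)
    buffer_add(buf, trans)
    if (buf$n >= cfg$batch_size) {
      batch <- buffer_sample(buf, cfg$batch_size)
      state <- ddpg_update(state, batch)
    }
    if (verbose && t %% 100 == 0)
      message(sprintf("finetune step %d | critic loss %.4g", t,
                      state$critic_loss %||% NA))
  }
  agent$actor <- state$actor
  agent$critic <- state$critic
  agent$actor_target <- state$actor_target
  agent$critic_target <- state$critic_target
  agent$finetune_curve <- data.frame(steps = steps,
                                     noise_sigma = noise_sigma)
  agent
}
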