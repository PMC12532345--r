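# shared fixtures, built in code

test_params <- function(...) oct_params(...)

test_phantom <- function(...) make_phantom(...)

phantom_mid_zf_test <- function(ph, p) octfocus:::phantom_mid_zf(ph, p)

# render a reference/target pair focused on different retinal bands (the
# focus travels with the retina under motion), a known integer pixel shift
# of the target, and rendering noise on
make_crossfocus_pair <- function(phantom, params, shift_px,
                                 ref_band = c("outer", "inner"),
                                 tgt_band = c("inner", "outer")) {
  ref_band <- match.arg(ref_band)
  tgt_band <- match.arg(tgt_band)
  band_zf <- function(band) {
    ctr <- if (band == "inner") phantom$inner_band_center
           else phantom$outer_band_center
    (ctr - 1) * params$axial_pixel_pitch
  }
  shift_um <- shift_px * params$axial_pixel_pitch
  ref <- render_bscan(phantom, focus_state(band_zf(ref_band), 0, 0, params),
                      params)
  tgt <- render_bscan(phantom,
                      focus_state(band_zf(tgt_band), 0, shift_um, params),
                      params)
  list(ref = ref, tgt = tgt, true_shift_px = shift_px)
}

# a focus_agent wrapper around freshly initialized (untrained) networks,
# for plumbing tests that do not need a converged policy
make_untrained_agent <- function(params = oct_params(),
                                 phantom = make_phantom(),
                                 config = agent_config(), seed = 1L) {
  set.seed(seed)
  actor <- octfocus:::build_actor(2L * config$M, params$n_depth_pixels)
  critic <- octfocus:::build_critic(2L * config$M, params$n_depth_pixels)
  structure(list(actor = actor, critic = critic,
                 actor_target = octfocus:::nn_deep_copy(actor),
                 critic_target = octfocus:::critic_deep_copy(critic),
                 config = config, phantom = phantom, params = params,
                 curve = NULL,
                 final_eval = list(mean_abs_error = NA_real_,
                                   mean_reward = NA_real_,
                                   errors = numeric(0))),
            class = "focus_agent")
}

# batch-averaged directly rendered channels at focus f (matches the sweep's
# batch acquisition, including the shared noise-floor pedestal)
batch_direct_channels <- function(phantom, params, f, n = 4, M = 4,
                                  smoothing_sigma = 2) {
  src <- sweep_source_simulator(phantom, params)
  img <- src(f)$intensity
  for (j in seq_len(n - 1)) img <- img + src(f)$intensity
  subregion_channels(img / n, M, smoothing_sigma)$channels
}

# memoised trained agent shared by the acceptance tests: trained once per
# test run at desk scale, reused by every block that needs a converged policy
trained_agent_cache <- new.env(parent = emptyenv())

get_trained_agent <- function() {
  if (is.null(trained_agent_cache$agent)) {
    cfg <- agent_config(rng_seed = 20240901L)
    trained_agent_cache$agent <-
      train_focus_agent(config = cfg, verbose = FALSE)
  }
  trained_agent_cache$agent
}
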