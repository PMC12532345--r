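# Actor and critic network constructors for the focus-correction agent.
#
# Actor: two blocks of [1D conv (kernel 3) -> ReLU -> max-pool (kernel 2)]
# growing 2M -> 16 -> 32 channels, flattened into a fully connected chain of
# 128, 64, 32 ReLU units, and a single tanh output in (-1, 1).
#
# Critic: an independent, critic-owned copy of the actor trunk compresses
# the observation to a single value; that value is concatenated with the
# focus-correction action and fed through a deep feed-forward stack of
# 500, 1000, 1000, 1000, 1000, 500, 200 ReLU units to one linear reward
# estimate.

actor_layer_specs <- function(in_channels, depth, output_init = 3e-3) {
  l1 <- depth - 2L
  p1 <- l1 %/% 2L
  l2 <- p1 - 2L
  p2 <- l2 %/% 2L
  flat <- 32L * p2
  list(
    list(type = "conv1d", in_ch = in_channels, out_ch = 16L, kernel = 3L),
    list(type = "relu"),
    list(type = "maxpool", k = 2L),
    list(type = "conv1d", in_ch = 16L, out_ch = 32L, kernel = 3L),
    list(type = "relu"),
    list(type = "maxpool", k = 2L),
    list(type = "flatten"),
    list(type = "dense", n_in = flat, n_out = 128L),
    list(type = "relu"),
    list(type = "dense", n_in = 128L, n_out = 64L),
    list(type = "relu"),
    list(type = "dense", n_in = 64L, n_out = 32L),
    list(type = "relu"),
    list(type = "dense", n_in = 32L, n_out = 1L, init_scale = output_init),
    list(type = "tanh")
  )
}

critic_head_specs <- function() {
  sizes <- c(2L, 500L, 1000L, 1000L, 1000L, 1000L, 500L, 200L)
  specs <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    specs <- c(specs, list(list(type = "dense", n_in = sizes[i],
                                n_out = sizes[i + 1L])),
               list(list(type = "relu")))
  }
  c(specs, list(list(type = "dense", n_in = 200L, n_out = 1L,
                     init_scale = 3e-3)))
}

build_actor <- function(in_channels, depth) {
  net <- nn_network(actor_layer_specs(in_channels, depth))
  net$in_channels <- in_channels
  net$depth <- depth
  net
}

build_critic <- function(in_channels, depth) {
  # The trunk mirrors the actor's conv/FC architecture but its single-value
  # embedding output is LINEAR with ordinary init, unlike the actor's
  # near-zero tanh policy head: a tanh here starts deep in saturation
  # (ReLU activations give the pre-activation a large fixed offset) and a
  # few coherent critic updates pin it at +-1, where its gradient is exactly
  # zero and the trunk can never learn. The embedding must both vary across
  # observations and keep a live gradient.
  specs <- actor_layer_specs(in_channels, depth, output_init = NULL)
  specs <- specs[-length(specs)]      # drop the tanh
  list(trunk = nn_network(specs),
       head = nn_network(critic_head_specs()),
       in_channels = in_channels, depth = depth)
}

# accept a single observation matrix [2M x depth] or a batch array
# [B x 2M x depth]
as_obs_batch <- function(obs) {
  if (is.matrix(obs)) {
    array(obs, dim = c(1L, nrow(obs), ncol(obs)))
  } else obs
}

#' Actor forward pass
#'
#' Maps an observation (or a batch of observations) through the actor
#' network to a focus-correction action in (-1, 1). Deterministic given the
#' weights.
#'
#' @param actor An actor network (internal; see [train_focus_agent()]).
#' @param obs A `2M x depth` matrix or a `B x 2M x depth` array.
#' @return Numeric vector of actions, one per observation.
#' @keywords internal
actor_forward <- function(actor, obs) {
  as.numeric(nn_forward(actor, as_obs_batch(obs))$out)
}

#' Critic forward pass
#'
#' Estimates the immediate reward of applying `action` given `obs`: the
#' observation is compressed to a single value by the critic's own copy of
#' the actor trunk, concatenated with the action, and passed through the
#' deep feed-forward head.
#'
#' @param critic A critic network pair (trunk + head).
#' @param obs A `2M x depth` matrix or `B x 2M x depth` array.
#' @param action Numeric vector (length B) of actions.
#' @return Numeric vector of reward estimates.
#' @keywords internal
critic_forward <- function(critic, obs, action) {
  e <- nn_forward(critic$trunk, as_obs_batch(obs))$out
  h <- nn_forward(critic$head, cbind(as.numeric(e), action))$out
  as.numeric(h)
}

# critic forward with caches plus backward pass; `dloss_fn(q)` supplies the
# loss gradient wrt the critic output after the forward pass, so the value
# and its gradient cost one pass each. With param_grads = FALSE only the
# gradient wrt the action input is computed (actor update path).
critic_forward_backward <- function(critic, obs_batch, action, dloss_fn,
                                    param_grads = TRUE,
                                    trunk_backward = TRUE) {
  fw_t <- nn_forward(critic$trunk, obs_batch, keep_cache = trunk_backward)
  xin <- cbind(as.numeric(fw_t$out), action)
  fw_h <- nn_forward(critic$head, xin, keep_cache = TRUE)
  q <- as.numeric(fw_h$out)
  bw_h <- nn_backward(critic$head, fw_h$caches,
                      matrix(dloss_fn(q), ncol = 1), param_grads)
  d_in <- bw_h$dx                     # [B x 2]: d(emb), d(action)
  bw_t <- if (trunk_backward)
    nn_backward(critic$trunk, fw_t$caches,
                matrix(d_in[, 1], ncol = 1), param_grads)
  list(q = q,
       grads_head = bw_h$grads,
       grads_trunk = if (trunk_backward) bw_t$grads,
       d_action = d_in[, 2])
}
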