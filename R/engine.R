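# Interface to the compiled simulation engine. The engine advances the whole
# network (stimulus encoding, Poisson spiking, delayed leaky integration,
# optional STDP + ceiling + normalization) in one call; this file marshals
# the edge-list weight representation and the discretized STDP kernels.

flatten_weights <- function(weights) {
  pre <- unlist(lapply(weights$blocks, `[[`, "pre"), use.names = FALSE)
  post <- unlist(lapply(weights$blocks, `[[`, "post"), use.names = FALSE)
  w <- unlist(lapply(weights$blocks, `[[`, "w"), use.names = FALSE)
  sizes <- vapply(weights$blocks, function(b) length(b$w), integer(1))
  list(pre = pre - 1L, post = post - 1L, w = w,
       block_ptr = c(0L, cumsum(sizes)))
}

unflatten_weights <- function(template, w_flat) {
  out <- template
  off <- 0L
  for (bi in seq_along(out$blocks)) {
    m <- length(out$blocks[[bi]]$w)
    out$blocks[[bi]]$w <- w_flat[(off + 1L):(off + m)]
    off <- off + m
  }
  out
}

# Discretized STDP kernels for the buffered engine update, in units of
# timesteps of lag. kernel_a[k + 1] pairs a post spike now with a pre spike
# k steps ago (effective difference (k - delay_steps) * dt); kernel_b[k]
# pairs a pre spike now with a post spike k steps ago (difference
# (-k - delay_steps) * dt). The same-step pair lives in kernel_a only.
make_stdp_kernels <- function(config) {
  delay_steps <- as.integer(round(config$t_delay / config$dt))
  win_steps <- as.integer(ceiling(config$stdp_window / config$dt))
  ka_lags <- 0:(win_steps + delay_steps)
  kb_lags <- seq_len(max(win_steps - delay_steps, 0L))
  list(
    a = stdp_kernel((ka_lags - delay_steps) * config$dt, config),
    b = stdp_kernel((-kb_lags - delay_steps) * config$dt, config),
    delay_steps = delay_steps)
}

stim_code <- function(stim) {
  if (is.null(stim)) 0L else switch(stim$kind, moving = 1L, flash = 2L,
                                    stop("unknown stimulus kind"))
}

#' Run the compiled network engine
#'
#' Low-level driver around the compiled simulation loop. Most users want
#' [train_subpopulation()], [run_motion_trial()] or [run_flash_probe()]
#' instead. Draws from the R random number generator, so results are
#' reproducible under `set.seed()`.
#'
#' @param weights An `stdpnet_weights`.
#' @param config An `stdpnet_config`.
#' @param stim An `stdpnet_stimulus` or `NULL` (baseline input only).
#' @param n_steps Number of timesteps in the main loop.
#' @param plastic Apply STDP, the growth ceiling and stochastic
#'   normalization.
#' @param warmup_steps Baseline-activity steps before the main loop (fills
#'   the delay buffers); defaults to `2 * n_layers * t_delay / dt`, or 0
#'   when `forced_spikes` is given.
#' @param record_spikes Return a `(layer, neuron, step)` spike table.
#' @param record_rates Return per-layer rate matrices (`n_neurons x
#'   n_steps`).
#' @param snapshot_every Record full weight snapshots every this many steps.
#' @param forced_spikes Optional integer matrix `(n_layers * n_neurons) x
#'   n_steps` of scripted spikes (row `(l - 1) * n_neurons + i` is neuron
#'   `i` of layer `l`); replaces Poisson sampling, for controlled tests.
#' @return A list: `weights` (an `stdpnet_weights`), `weights_flat`,
#'   `max_ratio` (largest weight-to-max-starting-weight ratio seen),
#'   `spikes`, `norm_steps`, `snapshots`, `snapshot_steps`, `rates`,
#'   `final_rates`.
#' @export
run_engine <- function(weights, config, stim = NULL, n_steps,
                       plastic = FALSE, warmup_steps = NULL,
                       record_spikes = FALSE, record_rates = FALSE,
                       snapshot_every = 0L, forced_spikes = NULL) {
  fl <- flatten_weights(weights)
  kern <- make_stdp_kernels(config)
  if (is.null(warmup_steps)) {
    warmup_steps <- if (is.null(forced_spikes))
      as.integer(round(2 * config$n_layers * config$t_delay / config$dt))
    else 0L
  }
  caps <- config$ceiling_factor * weights$w_max_init
  if (!plastic) caps <- rep(Inf, length(caps))
  st <- if (is.null(stim)) list(kind = 0L, position0 = 0, velocity = 0,
                                onset = 0, offset = 0)
        else stim
  res <- run_network_cpp(
    n_neurons = weights$n_neurons, n_layers = weights$n_layers,
    edge_pre = fl$pre, edge_post = fl$post, block_ptr = fl$block_ptr,
    w_start = fl$w, w_cap = caps,
    n_steps = as.integer(n_steps), warmup_steps = as.integer(warmup_steps),
    stim_kind = stim_code(stim),
    stim_pos0 = st$position0, stim_vel = st$velocity,
    stim_onset = st$onset, stim_offset = st$offset,
    stim_amp = config$stim_gain * config$r_b,
    r_b = config$r_b, sigma_p = config$sigma_p,
    dt = config$dt, tau_m = config$tau_m,
    delay_steps = kern$delay_steps,
    plastic = plastic, lr_max = config$lr_max,
    ramp_steps = config$ramp_steps, norm_prob = config$norm_prob,
    kernA = kern$a, kernB = kern$b,
    record_spikes = record_spikes, record_rates = record_rates,
    snapshot_every = as.integer(snapshot_every),
    forced_spikes_ = forced_spikes)
  res$weights_flat <- res$weights
  res$weights <- unflatten_weights(weights, res$weights_flat)
  res
}
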