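#' Balanced STDP kernel
#'
#' The additive STDP weight-change factor for an effective pre/post timing
#' difference `delta_t` (ms): `c_p * exp(-delta_t / tau_p)` for positive
#' differences (pre before post, potentiation), exactly 0 at zero, and
#' `-c_d * exp(delta_t / tau_d)` for negative differences (post before pre,
#' depression). Differences beyond `window` in absolute value contribute
#' nothing. With equal coefficients and time constants the kernel is
#' antisymmetric.
#'
#' @param delta_t Effective timing difference(s), ms.
#' @param config An `stdpnet_config` supplying `c_p`, `c_d`, `tau_p`,
#'   `tau_d` and `stdp_window` (overridable via `...`-free arguments).
#' @param window Maximum `|delta_t|` considered, ms.
#' @return Dimensionless weight-change factor(s).
#' @export
stdp_kernel <- function(delta_t, config = network_config(),
                        window = config$stdp_window) {
  out <- numeric(length(delta_t))
  pos <- delta_t > 0 & delta_t <= window
  neg <- delta_t < 0 & delta_t >= -window
  out[pos] <- config$c_p * exp(-delta_t[pos] / config$tau_p)
  out[neg] <- -config$c_d * exp(delta_t[neg] / config$tau_d)
  out
}

#' Learning rate at a training step
#'
#' The learning rate ramps linearly from 0 at step 0 to `lr_max` at
#' `ramp_steps` (the first quarter of training by default) and stays flat
#' afterwards.
#'
#' @param t_step 0-based training step, in `[0, n_train_steps)`.
#' @param config An `stdpnet_config`.
#' @return The learning rate `p_t`.
#' @export
learning_rate_at <- function(t_step, config) {
  if (any(t_step < 0) || any(t_step >= config$n_train_steps))
    stop("t_step out of range [0, n_train_steps)")
  config$lr_max * pmin(1, t_step / config$ramp_steps)
}

#' Spike-history container for incremental STDP
#'
#' Per (layer, neuron) lists of recent spike times within the pairing
#' horizon (`stdp_window + t_delay` ms, the largest lag that can still pair
#' with a future spike).
#'
#' @param config An `stdpnet_config`.
#' @return An object of class `stdpnet_history`.
#' @export
new_spike_history <- function(config) {
  structure(list(times = lapply(seq_len(config$n_layers), function(l)
    lapply(seq_len(config$n_neurons), function(i) numeric(0))),
    horizon = config$stdp_window + config$t_delay),
    class = "stdpnet_history")
}

#' Record one timestep of spikes into a history
#'
#' Appends spike time `t` for every spiking neuron and drops entries older
#' than the pairing horizon.
#'
#' @param history An `stdpnet_history`.
#' @param spikes Logical matrix `n_layers x n_neurons`.
#' @param t Current time, ms.
#' @return The updated history.
#' @export
record_spikes <- function(history, spikes, t) {
  cutoff <- t - history$horizon
  for (l in seq_len(nrow(spikes))) {
    for (i in which(spikes[l, ])) {
      v <- history$times[[l]][[i]]
      v <- v[v >= cutoff]
      history$times[[l]][[i]] <- c(v, t)
    }
  }
  history
}

#' Apply one timestep of STDP (reference implementation)
#'
#' All-to-all additive pairing: every connection `(j, i)` changes by
#' `p_t * F((t_j - t_i) - t_delay)` summed over the pre/post spike pairs
#' whose effective timing difference lies within the STDP window and that
#' involve at least one spike from the current timestep (older pairs were
#' applied on earlier calls). The transmission delay is subtracted from the
#' raw difference, so a presynaptic spike arriving exactly with the
#' postsynaptic spike produces zero change. Weights are floored at zero.
#'
#' The history must already contain the current timestep's spikes (call
#' [record_spikes()] first); `new_spikes` marks which of those are new.
#'
#' @param weights An `stdpnet_weights`.
#' @param history An `stdpnet_history` including the current spikes.
#' @param new_spikes Logical matrix `n_layers x n_neurons` of this step's
#'   spikes.
#' @param t Current time, ms.
#' @param p_t Learning rate for this step.
#' @param config An `stdpnet_config`.
#' @return The updated `stdpnet_weights`.
#' @export
apply_stdp <- function(weights, history, new_spikes, t, p_t, config) {
  if (p_t == 0) return(weights)
  for (bi in seq_along(weights$blocks)) {
    b <- weights$blocks[[bi]]
    pre_l <- bi
    post_l <- bi + 1L
    post_now <- new_spikes[post_l, ]
    pre_now <- new_spikes[pre_l, ]
    if (!any(post_now) && !any(pre_now)) next
    dw <- numeric(length(b$w))
    for (e in seq_along(b$w)) {
      j <- b$post[e]; i <- b$pre[e]
      acc <- 0
      if (post_now[j]) {
        # post spike now against all pre spikes in the horizon (incl. now)
        ti <- history$times[[pre_l]][[i]]
        if (length(ti) > 0)
          acc <- acc + sum(stdp_kernel(t - ti - config$t_delay, config))
      }
      if (pre_now[i]) {
        # pre spike now against strictly past post spikes (now handled above)
        tj <- history$times[[post_l]][[j]]
        tj <- tj[tj < t]
        if (length(tj) > 0)
          acc <- acc + sum(stdp_kernel(tj - t - config$t_delay, config))
      }
      dw[e] <- acc
    }
    w <- b$w + p_t * dw
    w[w < 0] <- 0
    weights$blocks[[bi]]$w <- w
  }
  weights
}

#' Clamp weights at the growth ceiling
#'
#' No weight may exceed `factor` times the maximum starting weight of its
#' inter-layer block (recorded at initialization); larger values are
#' clamped.
#'
#' @param weights An `stdpnet_weights`.
#' @param factor Ceiling multiple (default from the stored config value 3
#'   must be passed by the caller).
#' @return The clamped weights.
#' @export
apply_ceiling <- function(weights, factor = 3) {
  for (bi in seq_along(weights$blocks)) {
    cap <- factor * weights$w_max_init[bi]
    w <- weights$blocks[[bi]]$w
    w[w > cap] <- cap
    weights$blocks[[bi]]$w <- w
  }
  weights
}

#' Normalize incoming weights to unit sum
#'
#' Divides each postsynaptic neuron's incoming weights by their sum, so
#' every incoming sum is exactly 1 afterwards (the operation is idempotent).
#' A neuron whose incoming sum is zero cannot be normalized; this raises an
#' error naming the layer and neuron.
#'
#' @param weights An `stdpnet_weights`.
#' @return The normalized weights.
#' @export
normalize_incoming <- function(weights) {
  for (bi in seq_along(weights$blocks)) {
    b <- weights$blocks[[bi]]
    sums <- incoming_sums(weights, bi)
    bad <- which(sums[unique(b$post)] == 0)
    if (length(bad) > 0) {
      nrn <- unique(b$post)[bad[1]]
      stop(sprintf("cannot normalize: neuron %d in layer %d has zero incoming weight sum",
                   nrn, bi + 1L))
    }
    weights$blocks[[bi]]$w <- b$w / sums[b$post]
  }
  weights
}

#' Train one velocity-tuned subpopulation
#'
#' For a positive velocity, runs `n_runs` independent training simulations
#' of `n_train_steps` timesteps each. In every run a point stimulus starts
#' at a random position and moves continuously at the given velocity; STDP
#' is applied at every timestep with the ramped learning rate, the growth
#' ceiling is enforced after every update, and a weight-normalization event
#' fires with probability `norm_prob` per step. The runs share one
#' connectivity graph (so element-wise averaging is well defined) but draw
#' independent initial-weight jitter, start positions and Poisson noise; the
#' returned weights are the element-wise mean of the runs' final weights.
#'
#' For velocity 0 (the static network) no training is performed: the
#' function returns freshly initialized weights untouched, since balanced
#' STDP with non-directional input leaves symmetric weights unchanged in
#' expectation.
#'
#' @param config An `stdpnet_config`.
#' @param velocity Stimulus velocity, cycles/s.
#' @param graph Optional pre-built `stdpnet_connectivity` (built from the
#'   config otherwise).
#' @param snapshot_every If positive, record full weight snapshots every
#'   this many steps (averaged across runs in the log).
#' @param seed Optional seed applied before the first draw; the default
#'   leaves the RNG state alone.
#' @return An `stdpnet_weights` with attributes filled in, and a `log`
#'   attribute: a list with per-run `max_ratio`, normalization-event steps,
#'   and (optionally) averaged weight snapshots.
#' @export
train_subpopulation <- function(config, velocity, graph = NULL,
                                snapshot_every = 0L, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(graph)) graph <- build_connectivity(config)
  if (velocity == 0) {
    wt <- init_weights(graph, config)
    wt$velocity <- 0
    attr(wt, "log") <- list(max_ratio = 1, norm_steps = integer(0),
                            snapshots = NULL)
    return(wt)
  }
  runs <- vector("list", config$n_runs)
  max_ratios <- numeric(config$n_runs)
  norm_counts <- integer(config$n_runs)
  snap_acc <- NULL
  snap_steps <- NULL
  template <- NULL
  for (r in seq_len(config$n_runs)) {
    wt <- init_weights(graph, config)
    if (is.null(template)) template <- wt
    stim <- stimulus_moving(stats::runif(1), velocity)
    res <- run_engine(wt, config, stim, n_steps = config$n_train_steps,
                      plastic = TRUE, snapshot_every = snapshot_every)
    runs[[r]] <- res$weights_flat
    max_ratios[r] <- res$max_ratio
    norm_counts[r] <- length(res$norm_steps)
    if (snapshot_every > 0) {
      mat <- do.call(cbind, res$snapshots)
      snap_acc <- if (is.null(snap_acc)) mat else snap_acc + mat
      snap_steps <- res$snapshot_steps
    }
  }
  w_mean <- Reduce(`+`, runs) / config$n_runs
  out <- unflatten_weights(template, w_mean)
  out$velocity <- velocity
  out$trained <- TRUE
  # the ceiling reference of the averaged tensor: mean of the runs' caps is
  # not tracked per run; keep the template's (jitter makes them near-equal)
  attr(out, "log") <- list(
    max_ratio = max(max_ratios), max_ratio_runs = max_ratios,
    norm_counts = norm_counts,
    snapshots = if (is.null(snap_acc)) NULL else snap_acc / config$n_runs,
    snapshot_steps = snap_steps)
  out
}
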