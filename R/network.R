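#' Build the feedforward connectivity graph
#'
#' For each pair of consecutive layers, a connection from presynaptic neuron
#' `i` to postsynaptic neuron `j` in the layer above exists with probability
#' `exp(-d^2 / (2 sigma_w^2))`, where `d` is the signed circular distance
#' between the neurons' preferred positions. The profile peaks at probability
#' 1 for aligned neurons, which makes the expected number of incoming
#' connections per neuron `N_n * sigma_w * sqrt(2*pi)` (about 157 at the
#' default scale). Every block is drawn independently from the same rule.
#' A postsynaptic neuron ending up with no incoming connection has its row
#' resampled, so the graph never contains a disconnected neuron (which would
#' make weight normalization ill-defined).
#'
#' Candidate presynaptic partners are restricted to a window of
#' `ceiling(8 * sigma_w * n)` index offsets on either side; outside that
#' window the connection probability is below 1e-13 and is treated as zero.
#'
#' @param config An `stdpnet_config`. Uses `n_neurons`, `n_layers`,
#'   `sigma_w`.
#' @return An object of class `stdpnet_connectivity`: a list with `blocks`
#'   (per inter-layer block, a list with integer vectors `pre` and `post`,
#'   sorted by `post`), `n_w` (realized mean incoming connection count),
#'   `n_neurons` and `n_layers`.
#' @export
build_connectivity <- function(config) {
  validate_config(config)
  n <- config$n_neurons
  half <- min(ceiling(8 * config$sigma_w * n), floor((n - 1) / 2))
  offsets <- seq.int(-half, half)
  p_off <- exp(-(offsets / n)^2 / (2 * config$sigma_w^2))

  draw_block <- function() {
    keep <- matrix(stats::runif(n * length(offsets)) <
                     rep(p_off, each = n), nrow = n)
    # resample empty postsynaptic rows until each neuron has >= 1 input
    empty <- which(rowSums(keep) == 0L)
    while (length(empty) > 0L) {
      keep[empty, ] <- stats::runif(length(empty) * length(offsets)) <
        rep(p_off, each = length(empty))
      empty <- empty[rowSums(keep[empty, , drop = FALSE]) == 0L]
    }
    idx <- which(keep, arr.ind = TRUE)
    post <- idx[, 1L]
    pre <- ((post - 1L + offsets[idx[, 2L]]) %% n) + 1L
    o <- order(post, pre)
    list(pre = as.integer(pre[o]), post = as.integer(post[o]))
  }

  blocks <- lapply(seq_len(config$n_layers - 1L), function(b) draw_block())
  n_edges <- sum(vapply(blocks, function(b) length(b$pre), integer(1)))
  graph <- list(blocks = blocks,
                n_w = n_edges / (n * (config$n_layers - 1L)),
                n_neurons = n, n_layers = config$n_layers)
  class(graph) <- "stdpnet_connectivity"
  graph
}

#' @export
print.stdpnet_connectivity <- function(x, ...) {
  cat(sprintf("<stdpnet_connectivity> %d layers x %d neurons, %d blocks, mean incoming n_w = %.1f\n",
              x$n_layers, x$n_neurons, length(x$blocks), x$n_w))
  invisible(x)
}

#' Initialize feedforward weights on a connectivity graph
#'
#' Every existing connection starts at `w_init = 1 / n_w` (the reciprocal of
#' the realized mean connection count), plus independent uniform jitter on
#' `[-jitter, +jitter]`, clipped at zero so weights are never negative. With
#' the default geometry each neuron's incoming sum starts near 1, which is
#' the value the normalization step maintains.
#'
#' @param graph An `stdpnet_connectivity`.
#' @param config An `stdpnet_config` (for `ceiling_factor`).
#' @param jitter Half-width of the uniform initialization jitter.
#' @return An object of class `stdpnet_weights`: the graph's edge lists plus
#'   numeric weights `w` per block, the per-block maximum starting weight
#'   `w_max_init` (the reference for the growth ceiling), and `n_w`.
#' @export
init_weights <- function(graph, config, jitter = 0.025) {
  stopifnot(inherits(graph, "stdpnet_connectivity"))
  w_init <- 1 / graph$n_w
  blocks <- lapply(graph$blocks, function(b) {
    w <- w_init + stats::runif(length(b$pre), -jitter, jitter)
    w[w < 0] <- 0
    list(pre = b$pre, post = b$post, w = w)
  })
  wt <- list(blocks = blocks,
             w_max_init = vapply(blocks, function(b) max(b$w), numeric(1)),
             n_w = graph$n_w,
             n_neurons = graph$n_neurons, n_layers = graph$n_layers,
             velocity = NA_real_, trained = FALSE)
  class(wt) <- "stdpnet_weights"
  wt
}

#' @export
print.stdpnet_weights <- function(x, ...) {
  lab <- if (isTRUE(x$trained)) sprintf("trained (v = %g cycles/s)", x$velocity)
         else "untrained"
  cat(sprintf("<stdpnet_weights> %s; %d layers x %d neurons, n_w = %.1f\n",
              lab, x$n_layers, x$n_neurons, x$n_w))
  for (b in seq_along(x$blocks))
    cat(sprintf("  block %d->%d: %d edges, mean incoming sum %.4f\n",
                b, b + 1, length(x$blocks[[b]]$w),
                mean(incoming_sums(x, b))))
  invisible(x)
}

#' Per-neuron incoming weight sums of a block
#'
#' @param weights An `stdpnet_weights`.
#' @param block Inter-layer block index (1 = input layer to layer 2).
#' @return Numeric vector of length `n_neurons`.
#' @export
incoming_sums <- function(weights, block) {
  b <- weights$blocks[[block]]
  as.numeric(rowsum_by(b$w, b$post, weights$n_neurons))
}

# sum x grouped by 1-based index into 1..n
rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# sparse matrix view of one weight block (post x pre)
block_matrix <- function(weights, block) {
  b <- weights$blocks[[block]]
  Matrix::sparseMatrix(i = b$post, j = b$pre, x = b$w,
                       dims = c(weights$n_neurons, weights$n_neurons))
}

same_graph <- function(a, b) {
  if (a$n_neurons != b$n_neurons || a$n_layers != b$n_layers) return(FALSE)
  for (k in seq_along(a$blocks)) {
    if (!identical(a$blocks[[k]]$pre, b$blocks[[k]]$pre) ||
        !identical(a$blocks[[k]]$post, b$blocks[[k]]$post)) return(FALSE)
  }
  TRUE
}

#' Moving point stimulus
#'
#' A point stimulus on the ring whose position at time `t` ms is
#' `(position0 + velocity * t / 1000) mod 1`.
#'
#' @param position0 Start position, cycles in `[0, 1)`.
#' @param velocity Velocity, cycles/s.
#' @param onset,offset Stimulus on-interval, ms (default: always on).
#' @return An object of class `stdpnet_stimulus`.
#' @export
stimulus_moving <- function(position0, velocity, onset = 0, offset = Inf) {
  structure(list(kind = "moving", position0 = wrap_position(position0),
                 velocity = velocity, onset = onset, offset = offset),
            class = "stdpnet_stimulus")
}

#' Stationary flash stimulus
#'
#' A stationary point stimulus presented for a fixed duration (20 ms by
#' default), used as the probe delivered to the static network.
#'
#' @param position Flash position, cycles.
#' @param onset Flash onset, ms.
#' @param duration Flash duration, ms.
#' @return An object of class `stdpnet_stimulus`.
#' @export
stimulus_flash <- function(position, onset = 0, duration = 20) {
  structure(list(kind = "flash", position0 = wrap_position(position),
                 velocity = 0, onset = onset, offset = onset + duration),
            class = "stdpnet_stimulus")
}

#' Stimulus position at a time point
#'
#' @param stim An `stdpnet_stimulus`.
#' @param t Time, ms (vectorized).
#' @return Position(s) in `[0, 1)`.
#' @export
stimulus_position <- function(stim, t) {
  wrap_position(stim$position0 + stim$velocity * t / 1000)
}

#' Input-layer firing-rate profile for a stimulus
#'
#' While the stimulus is on, neuron `j` fires at
#' `r_b + A * exp(-d_j^2 / (2 sigma_p^2))` (wrapped), where `d_j` is the
#' circular distance from the neuron's preferred position to the stimulus
#' position and the amplitude `A = stim_gain * r_b` (100 Hz above the 5 Hz
#' baseline by default, i.e. a 105 Hz peak). When the stimulus is off, every
#' neuron fires at the baseline rate.
#'
#' @param stim An `stdpnet_stimulus` (or `NULL` for baseline only).
#' @param t Time, ms.
#' @param config An `stdpnet_config`.
#' @return Rate vector over the input layer, Hz.
#' @export
stimulus_rate_profile <- function(stim, t, config) {
  rates <- rep(config$r_b, config$n_neurons)
  if (is.null(stim) || t < stim$onset || t >= stim$offset) return(rates)
  pos <- stimulus_position(stim, t)
  d <- circular_distance(neuron_positions(config$n_neurons), pos)
  rates + config$stim_gain * config$r_b * wrapped_gaussian(d, config$sigma_p)
}

#' Draw Poisson spikes for one timestep
#'
#' Each neuron spikes independently with probability `r * dt / 1000`
#' (rates in Hz, `dt` in ms). Probabilities above 1 (rates beyond
#' `1000 / dt` Hz) are clamped with a warning.
#'
#' @param rates Rate vector, Hz; must be nonnegative.
#' @param dt Timestep, ms.
#' @return Logical spike vector.
#' @export
generate_spikes <- function(rates, dt) {
  stopifnot(all(rates >= 0))
  p <- rates * dt / 1000
  if (any(p > 1)) {
    warning("spike probability r*dt exceeds 1 for ", sum(p > 1),
            " neuron(s); clamped")
    p <- pmin(p, 1)
  }
  stats::runif(length(p)) < p
}

#' Leaky rate integration of delayed presynaptic spikes
#'
#' One timestep of the higher-layer dynamics:
#' `r_j(t) = r_j(t - dt) * exp(-dt / tau_m) + (dt / tau_m) * I_j(t)` with
#' `I_j(t) = (1000 / dt) * sum_i W_ji S_i(t - t_delay)` (rates in Hz, times
#' in ms; the factor `1000 / dt` converts spike counts per step into Hz, so
#' a presynaptic population firing at rate `r` through weights summing to 1
#' yields a steady state of `r * (dt / tau_m) / (1 - exp(-dt / tau_m))`,
#' i.e. approximately `r`).
#'
#' @param prev_rate Rate vector at `t - dt`, Hz.
#' @param delayed_spikes Logical/0-1 spike vector of the layer below from
#'   exactly `t_delay` earlier.
#' @param weights An `stdpnet_weights`.
#' @param block Which inter-layer block feeds this layer.
#' @param config An `stdpnet_config`.
#' @return Updated rate vector, Hz.
#' @export
integrate_layer <- function(prev_rate, delayed_spikes, weights, block, config) {
  if (length(delayed_spikes) != weights$n_neurons ||
      length(prev_rate) != weights$n_neurons)
    stop("dimension mismatch between rates/spikes and weight block")
  W <- block_matrix(weights, block)
  I <- (1000 / config$dt) * as.numeric(W %*% as.numeric(delayed_spikes))
  prev_rate * exp(-config$dt / config$tau_m) + (config$dt / config$tau_m) * I
}

#' Initialize the network state
#'
#' Sets up per-layer rates (baseline at the input layer, zero above), the
#' per-layer spike-delay buffers spanning `t_delay / dt` timesteps, and the
#' clock. Buffers start empty; use [warmup_state()] (or the engine's built-in
#' warm-up) to fill them with baseline activity before measuring anything.
#'
#' @param config An `stdpnet_config`.
#' @return An object of class `stdpnet_state`.
#' @export
init_network_state <- function(config) {
  D <- as.integer(round(config$t_delay / config$dt))
  st <- list(
    rates = rbind(rep(config$r_b, config$n_neurons),
                  matrix(0, config$n_layers - 1L, config$n_neurons)),
    spikes = matrix(FALSE, config$n_layers, config$n_neurons),
    buffers = lapply(seq_len(config$n_layers), function(l)
      matrix(FALSE, D, config$n_neurons)),
    buf_len = D, buf_pos = 0L, t = 0)
  class(st) <- "stdpnet_state"
  st
}

#' Advance the network by one timestep (reference implementation)
#'
#' Pure-R single-step update used for small networks and as the readable
#' reference for the compiled engine: input-layer rates are set from the
#' stimulus, each higher layer integrates the spikes of the layer below from
#' `t_delay` ago, spikes are drawn in every layer from the current rates via
#' the Poisson rule, the delay buffers rotate, and the clock advances by
#' `dt`.
#'
#' @param state An `stdpnet_state`.
#' @param weights An `stdpnet_weights`.
#' @param stim An `stdpnet_stimulus` or `NULL`.
#' @param config An `stdpnet_config`.
#' @return The updated state.
#' @export
step_network <- function(state, weights, stim, config) {
  if (is.null(state$buffers)) stop("uninitialized delay buffer")
  D <- state$buf_len
  # slot holding the spikes from exactly t_delay ago (about to be overwritten)
  slot <- (state$buf_pos %% D) + 1L
  state$rates[1L, ] <- stimulus_rate_profile(stim, state$t, config)
  for (l in seq(2L, config$n_layers)) {
    delayed <- state$buffers[[l - 1L]][slot, ]
    state$rates[l, ] <- integrate_layer(state$rates[l, ], delayed,
                                        weights, l - 1L, config)
  }
  for (l in seq_len(config$n_layers))
    state$spikes[l, ] <- generate_spikes(state$rates[l, ], config$dt)
  for (l in seq_len(config$n_layers))
    state$buffers[[l]][slot, ] <- state$spikes[l, ]
  state$buf_pos <- state$buf_pos + 1L
  state$t <- state$t + config$dt
  state
}

#' Warm up a network state with baseline activity
#'
#' Runs the network with no stimulus for `2 * n_layers * t_delay` ms
#' (by default) so that delay buffers carry baseline Poisson spikes and
#' higher-layer rates settle before measurement.
#'
#' @param state An `stdpnet_state`.
#' @param weights An `stdpnet_weights`.
#' @param config An `stdpnet_config`.
#' @param duration Warm-up duration, ms.
#' @return The warmed-up state (clock reset to 0).
#' @export
warmup_state <- function(state, weights, config,
                         duration = 2 * config$n_layers * config$t_delay) {
  steps <- as.integer(round(duration / config$dt))
  for (s in seq_len(steps))
    state <- step_network(state, weights, NULL, config)
  state$t <- 0
  state
}
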