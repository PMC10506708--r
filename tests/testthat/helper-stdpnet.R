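# Shared fixtures: all synthetic, built in code.

# a small but functional network configuration (temporal parameters at the
# reference values, sizes cut down)
tiny_config <- function(n_neurons = 60L, n_layers = 3L, ...) {
  reduced_profile(network_config(), n_neurons = n_neurons,
                  n_layers = n_layers, n_train_steps = 500L, n_runs = 2L,
                  velocities = c(0.5), ...)
}

# a minimal deterministic weight object on an explicit edge list, for
# plasticity unit tests (n small; single block unless stated)
manual_weights <- function(n_neurons, edges, w, n_layers = 2L) {
  # edges: list per block of cbind(post, pre)
  blocks <- lapply(seq_along(edges), function(bi) {
    e <- edges[[bi]]
    list(pre = as.integer(e[, 2]), post = as.integer(e[, 1]),
         w = as.numeric(w[[bi]]))
  })
  wt <- list(blocks = blocks,
             w_max_init = vapply(blocks, function(b) max(b$w), numeric(1)),
             n_w = mean(vapply(blocks, function(b) length(b$w), numeric(1))) /
               n_neurons,
             n_neurons = as.integer(n_neurons),
             n_layers = as.integer(n_layers),
             velocity = NA_real_, trained = FALSE)
  class(wt) <- "stdpnet_weights"
  wt
}

# independent brute-force STDP oracle: total weight change over a full
# scripted spike raster, enumerating every pre/post spike pair directly.
# spikes: list per layer of 0/1 matrices (n_neurons x n_steps).
# Returns the final weights (no floor/ceiling; caller must pick regimes
# where bounds never bind). Learning rate may vary per step (0-based).
stdp_oracle <- function(weights, spikes, config,
                        lr = function(s) config$lr_max) {
  n_steps <- ncol(spikes[[1]])
  out <- weights
  for (bi in seq_along(weights$blocks)) {
    b <- weights$blocks[[bi]]
    pre_times <- lapply(seq_len(config$n_neurons), function(i)
      which(spikes[[bi]][i, ] == 1) - 1L)      # 0-based step times
    post_times <- lapply(seq_len(config$n_neurons), function(j)
      which(spikes[[bi + 1L]][j, ] == 1) - 1L)
    for (e in seq_along(b$w)) {
      ti <- pre_times[[b$pre[e]]]
      tj <- post_times[[b$post[e]]]
      if (length(ti) == 0 || length(tj) == 0) next
      acc <- 0
      for (a in tj) for (bb in ti) {
        dtv <- (a - bb) * config$dt - config$t_delay
        if (abs(dtv) <= config$stdp_window && dtv != 0) {
          # the incremental scheme applies a pair when its later spike lands
          p <- lr(max(a, bb))
          acc <- acc + p * stdp_kernel(dtv, config)
        }
      }
      out$blocks[[bi]]$w[e] <- out$blocks[[bi]]$w[e] + acc
    }
  }
  out
}

# random scripted raster as a forced-spikes matrix + per-layer matrices
random_raster <- function(config, n_steps, p_spike = 0.08) {
  per_layer <- lapply(seq_len(config$n_layers), function(l)
    matrix(as.integer(stats::runif(config$n_neurons * n_steps) < p_spike),
           config$n_neurons, n_steps))
  forced <- do.call(rbind, per_layer)
  list(per_layer = per_layer, forced = forced)
}

flat_w <- function(weights) unlist(lapply(weights$blocks, `[[`, "w"),
                                   use.names = FALSE)
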