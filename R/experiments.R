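#' Deterministic rate-only propagation
#'
#' Propagates firing rates through the network without conversion to spikes:
#' the expected-input version of the spiking dynamics, where each higher
#' layer integrates `W %*% r(t - t_delay)` of the layer below. Layers start
#' at their deterministic baseline steady state. Used for the
#' activation-delay calibration and for fast post-training visualisation of
#' response time courses.
#'
#' @param weights An `stdpnet_weights`.
#' @param config An `stdpnet_config`.
#' @param stim An `stdpnet_stimulus` or `NULL`.
#' @param n_steps Timesteps to simulate.
#' @return List of `n_neurons x n_steps` rate matrices, one per layer.
#'   Column `s` holds the rates at time `t = (s - 1) * dt` ms.
#' @export
rate_propagation <- function(weights, config, stim, n_steps) {
  n <- config$n_neurons
  L <- config$n_layers
  D <- as.integer(round(config$t_delay / config$dt))
  a <- config$dt / config$tau_m
  decay <- exp(-config$dt / config$tau_m)
  gain <- a / (1 - decay)
  W <- lapply(seq_len(L - 1L), function(b) block_matrix(weights, b))

  # deterministic baseline steady state, layer by layer
  r <- vector("list", L)
  r[[1]] <- rep(config$r_b, n)
  for (l in seq_len(L - 1L))
    r[[l + 1]] <- gain * as.numeric(W[[l]] %*% r[[l]])

  out <- lapply(seq_len(L), function(l) matrix(0, n, n_steps))
  # per-layer history of the last D rate vectors (columns, circular)
  histories <- lapply(seq_len(L), function(l)
    matrix(r[[l]], n, D))
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * config$dt
    slot <- ((s - 1L) %% D) + 1L
    r_new <- vector("list", L)
    r_new[[1]] <- stimulus_rate_profile(stim, t, config)
    for (l in seq_len(L - 1L)) {
      delayed <- histories[[l]][, slot]
      r_new[[l + 1]] <- r[[l + 1]] * decay +
        a * as.numeric(W[[l]] %*% delayed)
    }
    for (l in seq_len(L)) {
      histories[[l]][, slot] <- r_new[[l]]
      out[[l]][, s] <- r_new[[l]]
      r[[l]] <- r_new[[l]]
    }
  }
  out
}

#' Calibrate per-layer activation delays
#'
#' The response of each layer to a brief flash peaks some time after the
#' earliest possible arrival of the stimulus information, because the leaky
#' membrane needs time to build up a response. This calibration runs the
#' deterministic rate-only network (untrained weights) with a 20 ms flash
#' and records, for the neuron best tuned to the flash position in each
#' layer, the time of its peak rate. The activation delay of layer `l` is
#' that peak time minus the earliest arrival `(l - 1) * t_delay`; the
#' comparison timepoint used by the measurement protocols is their sum
#' (i.e. the peak time itself), relative to flash onset.
#'
#' @param weights Untrained `stdpnet_weights`.
#' @param config An `stdpnet_config`.
#' @param flash_position Flash position, cycles.
#' @param flash_duration Flash duration, ms.
#' @param t_max Simulation horizon, ms (defaults to generous coverage of
#'   the last layer's peak).
#' @return A data.frame with columns `layer`, `earliest_ms`
#'   (`(l - 1) * t_delay`), `a_delay_ms`, `comparison_ms`. Deterministic.
#' @export
compute_activation_delays <- function(weights, config, flash_position = 0.5,
                                      flash_duration = 20, t_max = NULL) {
  if (is.null(t_max))
    t_max <- (config$n_layers - 1) * config$t_delay + flash_duration +
      12 * config$tau_m + 40
  n_steps <- as.integer(ceiling(t_max / config$dt))
  stim <- stimulus_flash(flash_position, onset = 0,
                         duration = flash_duration)
  rates <- rate_propagation(weights, config, stim, n_steps)
  idx <- which.min(abs(circular_distance(neuron_positions(config$n_neurons),
                                         flash_position)))
  out <- data.frame(layer = seq_len(config$n_layers),
                    earliest_ms = (seq_len(config$n_layers) - 1) *
                      config$t_delay,
                    a_delay_ms = NA_real_, comparison_ms = NA_real_)
  for (l in seq_len(config$n_layers)) {
    trace <- rates[[l]][idx, ]
    peak <- which.max(trace)
    if (peak == n_steps)
      stop("no rate peak within the calibration window for layer ", l)
    peak_ms <- (peak - 1) * config$dt
    out$a_delay_ms[l] <- peak_ms - out$earliest_ms[l]
    out$comparison_ms[l] <- peak_ms
  }
  out
}

#' Run one motion trial
#'
#' A point stimulus starts at a (by default random) position and moves at
#' the given velocity for the duration of the trial while the network,
#' with frozen weights (no STDP, no normalization), is simulated and all
#' spikes are recorded. The network is warmed up with baseline activity
#' before the trial starts.
#'
#' @param weights Trained (or untrained) `stdpnet_weights`.
#' @param velocity Stimulus velocity, cycles/s.
#' @param config An `stdpnet_config`.
#' @param start_position Start position in cycles; drawn uniformly on
#'   `[0, 1)` when `NULL`.
#' @param duration Trial duration, ms.
#' @return An object of class `stdpnet_trial`: list with `spikes` (integer
#'   matrix `layer`, `neuron`, `step`), `positions` (stimulus position per
#'   step), `velocity`, `start_position`, `duration`, `dt`.
#' @export
run_motion_trial <- function(weights, velocity, config,
                             start_position = NULL, duration = 700) {
  if (is.null(start_position)) start_position <- stats::runif(1)
  stim <- stimulus_moving(start_position, velocity)
  n_steps <- as.integer(round(duration / config$dt))
  res <- run_engine(weights, config, stim, n_steps = n_steps,
                    plastic = FALSE, record_spikes = TRUE)
  structure(list(spikes = res$spikes,
                 positions = stimulus_position(stim,
                                               (seq_len(n_steps) - 1) *
                                                 config$dt),
                 velocity = velocity, start_position = start_position,
                 duration = duration, dt = config$dt, n_steps = n_steps),
            class = "stdpnet_trial")
}

#' @export
print.stdpnet_trial <- function(x, ...) {
  cat(sprintf("<stdpnet_trial> %g ms at v = %g cycles/s from %.3f; %d spikes\n",
              x$duration, x$velocity, x$start_position, nrow(x$spikes)))
  invisible(x)
}

#' Run one stationary flash probe
#'
#' Presents a 20 ms (by default) stationary flash to the static (untrained)
#' network and records spikes for long enough to cover the last layer's
#' comparison timepoint.
#'
#' @param weights Static-network `stdpnet_weights`.
#' @param position Flash position, cycles.
#' @param config An `stdpnet_config`.
#' @param duration Flash duration, ms.
#' @param t_max Recording horizon, ms.
#' @return An `stdpnet_trial` (flash onset at t = 0, step 1).
#' @export
run_flash_probe <- function(weights, position, config, duration = 20,
                            t_max = NULL) {
  if (is.null(t_max))
    t_max <- (config$n_layers - 1) * config$t_delay + duration +
      12 * config$tau_m + 40
  stim <- stimulus_flash(position, onset = 0, duration = duration)
  n_steps <- as.integer(ceiling(t_max / config$dt))
  res <- run_engine(weights, config, stim, n_steps = n_steps,
                    plastic = FALSE, record_spikes = TRUE)
  structure(list(spikes = res$spikes,
                 positions = rep(wrap_position(position), n_steps),
                 velocity = 0, start_position = wrap_position(position),
                 duration = t_max, dt = config$dt, n_steps = n_steps),
            class = "stdpnet_trial")
}

#' Population spiking peak around a timepoint
#'
#' Pools a layer's spikes in a symmetric window of timesteps, smooths their
#' neuron positions with the wrapped-Gaussian kernel, and returns the peak
#' of the resulting density as the represented position.
#'
#' @param trial An `stdpnet_trial` (or a spike matrix with columns `layer`,
#'   `neuron`, `step`).
#' @param layer Layer index.
#' @param center_step Center of the pooling window (1-based step).
#' @param halfwidth_steps Half-width of the pooling window, steps.
#' @param config An `stdpnet_config` (for `kde_sigma` and `n_neurons`).
#' @return Peak position in cycles, or `NA` if the layer produced no spike
#'   in the window.
#' @export
spiking_peak <- function(trial, layer, center_step, halfwidth_steps,
                         config) {
  spikes <- if (inherits(trial, "stdpnet_trial")) trial$spikes else trial
  sel <- spikes[, "layer"] == layer &
    abs(spikes[, "step"] - center_step) <= halfwidth_steps
  if (!any(sel)) return(NA_real_)
  pos <- neuron_positions(config$n_neurons)[spikes[sel, "neuron"]]
  find_pdf_peak(smooth_to_pdf(pos, config$kde_sigma, config$n_neurons))
}

#' Spike-collection experiment: motion versus flash peak differences
#'
#' The measurement protocol for STDP-driven forward shifts: for each trial
#' a motion stimulus runs through the trained network for the trial
#' duration; at the trial midpoint a stationary flash is presented at the
#' motion stimulus's current location, as separate input to the static
#' (untrained) network. At each layer's comparison timepoint (flash onset
#' plus earliest arrival plus activation delay, from the deterministic
#' calibration) the circular difference between the motion network's and
#' the static network's population spiking peaks is recorded, signed
#' positive in the direction of motion. A von Mises distribution is fitted
#' per layer across trials.
#'
#' Trials in which a layer produced no spikes inside its evaluation window
#' are excluded for that layer and counted.
#'
#' @param trained_weights Trained `stdpnet_weights` for this velocity.
#' @param static_weights Untrained `stdpnet_weights` (the static network).
#' @param velocity Motion velocity, cycles/s.
#' @param config An `stdpnet_config`.
#' @param n_trials Number of trials.
#' @param delays Optional precomputed [compute_activation_delays()] table.
#' @param peak_halfwidth Spike-pooling half-window, ms.
#' @param trial_duration Motion-trial duration, ms.
#' @return A list with `table` (data.frame: `layer`, `mean_diff_cycles`,
#'   `kappa`, `se_cycles`, `n_used`, `n_excluded`) and `diffs` (trials x
#'   layers matrix of per-trial differences, NA where excluded).
#' @export
spike_collection_experiment <- function(trained_weights, static_weights,
                                        velocity, config, n_trials = 200,
                                        delays = NULL, peak_halfwidth = 5,
                                        trial_duration = 700) {
  if (is.null(delays))
    delays <- compute_activation_delays(static_weights, config)
  L <- config$n_layers
  hw <- as.integer(round(peak_halfwidth / config$dt))
  t_mid <- trial_duration / 2
  mid_step <- as.integer(round(t_mid / config$dt)) + 1L
  flash_horizon <- max(delays$comparison_ms) + peak_halfwidth + 10
  diffs <- matrix(NA_real_, n_trials, L)
  dirsign <- if (velocity < 0) -1 else 1
  for (tr in seq_len(n_trials)) {
    motion <- run_motion_trial(trained_weights, velocity, config,
                               duration = trial_duration)
    flash_pos <- motion$positions[mid_step]
    flash <- run_flash_probe(static_weights, flash_pos, config,
                             t_max = flash_horizon)
    for (l in seq_len(L)) {
      cmp <- delays$comparison_ms[l]
      m_step <- as.integer(round((t_mid + cmp) / config$dt)) + 1L
      f_step <- as.integer(round(cmp / config$dt)) + 1L
      pk_m <- spiking_peak(motion, l, m_step, hw, config)
      pk_f <- spiking_peak(flash, l, f_step, hw, config)
      if (!is.na(pk_m) && !is.na(pk_f))
        diffs[tr, l] <- dirsign * circular_distance(pk_m, pk_f)
    }
  }
  summarize_circular_table(diffs, "mean_diff_cycles")
}

#' Realtime representational lag experiment
#'
#' Measures, at the midpoint of each motion trial, the circular difference
#' between each layer's population spiking peak and the true concurrent
#' stimulus position (all layers evaluated at the same timepoint). Positive
#' values mean the represented position is ahead of the stimulus along the
#' motion direction; untrained networks show increasingly negative lag with
#' layer depth. A von Mises distribution is fitted per layer across trials.
#'
#' @param weights `stdpnet_weights` (trained or untrained).
#' @param velocity Motion velocity, cycles/s.
#' @param config An `stdpnet_config`.
#' @param n_trials Number of trials.
#' @param peak_halfwidth Spike-pooling half-window, ms.
#' @param trial_duration Trial duration, ms.
#' @return As [spike_collection_experiment()], with the per-layer mean lag
#'   in `mean_lag_cycles`.
#' @export
realtime_lag_experiment <- function(weights, velocity, config,
                                    n_trials = 200, peak_halfwidth = 5,
                                    trial_duration = 700) {
  L <- config$n_layers
  hw <- as.integer(round(peak_halfwidth / config$dt))
  t_mid <- trial_duration / 2
  mid_step <- as.integer(round(t_mid / config$dt)) + 1L
  dirsign <- if (velocity < 0) -1 else 1
  lags <- matrix(NA_real_, n_trials, L)
  for (tr in seq_len(n_trials)) {
    motion <- run_motion_trial(weights, velocity, config,
                               duration = trial_duration)
    true_pos <- motion$positions[mid_step]
    for (l in seq_len(L)) {
      pk <- spiking_peak(motion, l, mid_step, hw, config)
      if (!is.na(pk))
        lags[tr, l] <- dirsign * circular_distance(pk, true_pos)
    }
  }
  summarize_circular_table(lags, "mean_lag_cycles")
}

# von Mises summary of a trials x layers matrix of circular differences
summarize_circular_table <- function(vals, value_name) {
  L <- ncol(vals)
  tab <- data.frame(layer = seq_len(L), value = NA_real_,
                    kappa = NA_real_, se_cycles = NA_real_,
                    n_used = NA_integer_, n_excluded = NA_integer_)
  names(tab)[2] <- value_name
  for (l in seq_len(L)) {
    v <- vals[, l]
    ok <- !is.na(v)
    tab$n_used[l] <- sum(ok)
    tab$n_excluded[l] <- sum(!ok)
    if (sum(ok) >= 2) {
      fit <- fit_von_mises(2 * pi * v[ok])
      tab[[value_name]][l] <- fit$mu_cycles
      tab$kappa[l] <- fit$kappa
      tab$se_cycles[l] <- von_mises_se(fit, cycles = TRUE)
    }
  }
  list(table = tab, diffs = vals)
}

#' Alignment score from a realtime-lag table
#'
#' Applies [alignment_score()] to the per-layer mean realtime
#' representations of one network: the mean absolute circular deviation of
#' the layer-2-and-above mean lags from the input layer's mean lag.
#'
#' @param lag_table The `table` element returned by
#'   [realtime_lag_experiment()].
#' @return Nonnegative alignment score, cycles (0 = perfect alignment).
#' @export
realtime_alignment <- function(lag_table) {
  lag <- lag_table$mean_lag_cycles
  alignment_score(lag[-1], lag[1])
}

#' Sweep training and measurement over a velocity x tau_m grid
#'
#' Orchestrates, for every combination of velocity and membrane time
#' constant: training of the velocity-tuned subpopulation, an untrained
#' counterpart on the same connectivity graph, and the requested
#' measurements. Returns one tidy table keyed by (velocity, tau_m, network,
#' layer, metric).
#'
#' Available metrics: `rf_shift` (receptive-field shift per layer >= 2),
#' `lag` (realtime mean lag per layer, trained and untrained),
#' `alignment` (cross-layer alignment score, trained and untrained),
#' `peak_diff` (motion-versus-flash spiking peak difference per layer).
#'
#' @param config Base `stdpnet_config`.
#' @param velocities Velocities to sweep (default: the config's list).
#' @param tau_m_values Membrane time constants to sweep, ms.
#' @param measures Character vector of metrics (see above).
#' @param n_trials Trials per measurement experiment.
#' @param seed Master seed; each grid cell gets a deterministic child seed.
#' @param cache_dir Optional directory; finished cells are saved there and
#'   skipped on re-run (resumable sweeps).
#' @param verbose Print per-cell progress to stderr.
#' @return A tidy data.frame with columns `velocity`, `tau_m`, `network`,
#'   `layer` (NA for network-level metrics), `metric`, `value`, `n`.
#' @export
velocity_sweep <- function(config, velocities = config$velocities,
                           tau_m_values = config$tau_m,
                           measures = c("rf_shift", "lag", "alignment"),
                           n_trials = 50, seed = config$seed,
                           cache_dir = NULL, verbose = FALSE) {
  measures <- match.arg(measures,
                        c("rf_shift", "lag", "alignment", "peak_diff"),
                        several.ok = TRUE)
  out <- list()
  for (tau in tau_m_values) {
    for (v in velocities) {
      key <- sprintf("cell_v%s_tau%s", format(v), format(tau))
      if (!is.null(cache_dir)) {
        cache_file <- file.path(cache_dir, paste0(key, ".rds"))
        if (file.exists(cache_file)) {
          out[[key]] <- readRDS(cache_file)
          next
        }
      }
      if (verbose)
        message(sprintf("sweep: velocity %g, tau_m %g", v, tau))
      cfg <- config
      cfg$tau_m <- tau
      validate_config(cfg)
      set.seed(seed_stream(seed, round(1000 * v), round(10 * tau)))
      cell <- sweep_cell(cfg, v, measures, n_trials)
      cell$velocity <- v
      cell$tau_m <- tau
      out[[key]] <- cell
      if (!is.null(cache_dir)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(cell, cache_file)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("velocity", "tau_m", "network", "layer", "metric", "value", "n")]
}

sweep_cell <- function(cfg, v, measures, n_trials) {
  graph <- build_connectivity(cfg)
  untrained <- init_weights(graph, cfg)
  trained <- train_subpopulation(cfg, v, graph = graph)
  rows <- list()
  add <- function(network, layer, metric, value, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      network = network, layer = layer, metric = metric,
      value = value, n = n)
  }
  if ("rf_shift" %in% measures && v > 0) {
    for (l in 2:cfg$n_layers)
      add("trained", l, "rf_shift",
          measure_rf_shift(trained, untrained, l,
                           kernel_sigma = cfg$kde_sigma), 1L)
  }
  need_lag <- any(c("lag", "alignment") %in% measures)
  if (need_lag) {
    lag_tr <- realtime_lag_experiment(trained, v, cfg, n_trials = n_trials)
    lag_un <- realtime_lag_experiment(untrained, v, cfg,
                                      n_trials = n_trials)
    if ("lag" %in% measures) {
      for (l in seq_len(cfg$n_layers)) {
        add("trained", l, "lag", lag_tr$table$mean_lag_cycles[l],
            lag_tr$table$n_used[l])
        add("untrained", l, "lag", lag_un$table$mean_lag_cycles[l],
            lag_un$table$n_used[l])
      }
    }
    if ("alignment" %in% measures) {
      add("trained", NA_integer_, "alignment", realtime_alignment(lag_tr$table),
          n_trials)
      add("untrained", NA_integer_, "alignment",
          realtime_alignment(lag_un$table), n_trials)
    }
  }
  if ("peak_diff" %in% measures) {
    pd <- spike_collection_experiment(trained, untrained, v, cfg,
                                      n_trials = n_trials)
    for (l in seq_len(cfg$n_layers))
      add("trained", l, "peak_diff", pd$table$mean_diff_cycles[l],
          pd$table$n_used[l])
  }
  do.call(rbind, rows)
}
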