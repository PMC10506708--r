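#' Network configuration
#'
#' Builds the full parameter set of the simulation. The defaults are the
#' reference parameter values of the model: 6 layers of 2000 neurons on the
#' unit ring, Gaussian anatomical connectivity and input activation of width
#' 1/32 cycle, 5 Hz baseline Poisson firing, a 20 ms transmission delay
#' between consecutive layers, balanced STDP (`c_p = c_d = 1`,
#' `tau_p = tau_d = 20` ms), 1 ms timesteps, and a 10 ms membrane time
#' constant. Training runs for 20000 steps with the learning rate ramping
#' linearly from 0 to 4e-4 over the first quarter of training, weight
#' normalization firing with probability 0.01 per step, a growth ceiling of
#' 3 times the maximum starting weight, and 10 independent runs averaged per
#' velocity. The trained velocities are 0.1 to 1 cycles/s in steps of 0.1
#' plus 2, 3, 4 and 5 cycles/s.
#'
#' @param n_neurons Neurons per layer.
#' @param n_layers Number of layers (input layer included).
#' @param n_velocities Number of velocity-tuned subpopulations.
#' @param sigma_w Width of the anatomical connection-probability profile,
#'   cycles.
#' @param sigma_p Width of the input-layer activation profile, cycles.
#' @param r_b Baseline firing rate, Hz.
#' @param t_delay Inter-layer transmission delay, ms.
#' @param c_p,c_d STDP potentiation/depression coefficients.
#' @param tau_p,tau_d STDP time constants, ms.
#' @param dt Simulation timestep, ms.
#' @param tau_m Passive membrane time constant, ms.
#' @param n_train_steps Training duration in timesteps.
#' @param ramp_steps Length of the linear learning-rate ramp, timesteps.
#' @param lr_max Asymptotic learning rate.
#' @param stim_gain Stimulus magnitude as a multiple of `r_b` (peak of the
#'   activation bump above baseline).
#' @param ceiling_factor Growth ceiling as a multiple of the maximum starting
#'   weight of a block.
#' @param norm_prob Per-step probability of a weight-normalization event.
#' @param n_runs Independent training runs averaged per velocity.
#' @param velocities Stimulus velocities, cycles/s.
#' @param stdp_window Maximum absolute effective timing difference entering
#'   the STDP update, ms. The default, 7 times the slower STDP time
#'   constant, truncates the exponential kernel below 1e-3 of its peak.
#' @param kde_sigma Width of the wrapped-Gaussian smoothing kernel used in
#'   the analysis stage, cycles; defaults to `sigma_p`.
#' @param seed Master seed for the deterministic seed tree.
#' @return An object of class `stdpnet_config` (a validated named list).
#' @seealso [reduced_profile()], [load_config()]
#' @export
network_config <- function(n_neurons = 2000L,
                           n_layers = 6L,
                           n_velocities = 10L,
                           sigma_w = 1 / 32,
                           sigma_p = 1 / 32,
                           r_b = 5,
                           t_delay = 20,
                           c_p = 1,
                           c_d = 1,
                           tau_p = 20,
                           tau_d = 20,
                           dt = 1,
                           tau_m = 10,
                           n_train_steps = 20000L,
                           ramp_steps = NULL,
                           lr_max = 4e-4,
                           stim_gain = 20,
                           ceiling_factor = 3,
                           norm_prob = 0.01,
                           n_runs = 10L,
                           velocities = c(seq(0.1, 1, by = 0.1), 2, 3, 4, 5),
                           stdp_window = NULL,
                           kde_sigma = NULL,
                           seed = 1L) {
  if (is.null(ramp_steps)) ramp_steps <- as.integer(n_train_steps %/% 4)
  if (is.null(stdp_window)) stdp_window <- 7 * max(tau_p, tau_d)
  if (is.null(kde_sigma)) kde_sigma <- sigma_p
  cfg <- list(
    n_neurons = as.integer(n_neurons), n_layers = as.integer(n_layers),
    n_velocities = as.integer(n_velocities),
    sigma_w = sigma_w, sigma_p = sigma_p, r_b = r_b, t_delay = t_delay,
    c_p = c_p, c_d = c_d, tau_p = tau_p, tau_d = tau_d,
    dt = dt, tau_m = tau_m,
    n_train_steps = as.integer(n_train_steps),
    ramp_steps = as.integer(ramp_steps), lr_max = lr_max,
    stim_gain = stim_gain, ceiling_factor = ceiling_factor,
    norm_prob = norm_prob, n_runs = as.integer(n_runs),
    velocities = velocities, stdp_window = stdp_window,
    kde_sigma = kde_sigma, seed = as.integer(seed))
  class(cfg) <- "stdpnet_config"
  validate_config(cfg)
  cfg
}

#' Validate a network configuration
#'
#' Checks the structural invariants of the parameter set (positivity of time
#' constants, `dt <= tau_m`, widths in `(0, 0.5)`, at least two layers,
#' nonnegative velocities, a nonnegative learning-rate schedule). Called by
#' every constructor; exported so externally assembled configurations can be
#' checked too.
#'
#' @param config An `stdpnet_config` object.
#' @return The config, invisibly; errors with a field-level message on the
#'   first violated invariant.
#' @export
validate_config <- function(config) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg,
                                                 call. = FALSE)
  for (f in c("tau_p", "tau_d", "tau_m", "dt", "t_delay"))
    chk(is.numeric(config[[f]]) && length(config[[f]]) == 1 &&
          config[[f]] > 0, paste(f, "must be a positive scalar"))
  chk(config$dt <= config$tau_m, "dt must not exceed tau_m")
  for (f in c("sigma_w", "sigma_p", "kde_sigma"))
    chk(config[[f]] > 0 && config[[f]] < 0.5,
        paste(f, "must lie in (0, 0.5)"))
  chk(config$n_layers >= 2, "n_layers must be at least 2")
  chk(config$n_neurons >= 2, "n_neurons must be at least 2")
  chk(all(config$velocities >= 0), "velocities must be nonnegative")
  chk(config$r_b >= 0, "r_b must be nonnegative")
  chk(config$lr_max >= 0, "lr_max must be nonnegative")
  chk(config$ramp_steps >= 0, "ramp_steps must be nonnegative")
  chk(config$norm_prob >= 0 && config$norm_prob <= 1,
      "norm_prob must lie in [0, 1]")
  chk(config$ceiling_factor > 0, "ceiling_factor must be positive")
  chk(config$n_runs >= 1, "n_runs must be at least 1")
  chk(config$n_train_steps >= 1, "n_train_steps must be at least 1")
  chk(config$stdp_window > 0, "stdp_window must be positive")
  chk(abs(config$t_delay / config$dt -
            round(config$t_delay / config$dt)) < 1e-9,
      "t_delay must be an integer multiple of dt")
  invisible(config)
}

#' @export
print.stdpnet_config <- function(x, ...) {
  cat("<stdpnet_config>\n")
  cat(sprintf("  %d layers x %d neurons on [0,1); %d velocity subpopulations\n",
              x$n_layers, x$n_neurons, length(x$velocities)))
  cat(sprintf("  sigma_w = %.4g, sigma_p = %.4g cycles; r_b = %g Hz; stimulus peak = %g Hz\n",
              x$sigma_w, x$sigma_p, x$r_b, x$r_b + x$stim_gain * x$r_b))
  cat(sprintf("  dt = %g ms, tau_m = %g ms, t_delay = %g ms\n",
              x$dt, x$tau_m, x$t_delay))
  cat(sprintf("  STDP: c_p = %g, c_d = %g, tau_p = %g ms, tau_d = %g ms, window = %g ms\n",
              x$c_p, x$c_d, x$tau_p, x$tau_d, x$stdp_window))
  cat(sprintf("  training: %d steps, ramp %d, lr_max = %g, norm_prob = %g, ceiling %gx, %d runs\n",
              x$n_train_steps, x$ramp_steps, x$lr_max, x$norm_prob,
              x$ceiling_factor, x$n_runs))
  invisible(x)
}

#' Desk-scale configuration profile
#'
#' Returns a copy of the configuration scaled down for fast exploratory runs
#' (fewer neurons, layers, training steps, runs and velocities) while keeping
#' every temporal parameter (`dt`, `tau_m`, `t_delay`, `tau_p`, `tau_d`, the
#' STDP window) at its full-scale value, so that timing-dependent results
#' keep their structure.
#'
#' @param config A full-scale configuration.
#' @param n_neurons,n_layers,n_train_steps,n_runs,velocities Reduced sizes.
#' @return An `stdpnet_config`.
#' @export
reduced_profile <- function(config = network_config(),
                            n_neurons = 400L, n_layers = 4L,
                            n_train_steps = 5000L, n_runs = 3L,
                            velocities = c(0.2, 0.4, 0.6, 0.8, 1.0)) {
  cfg <- config
  cfg$n_neurons <- as.integer(n_neurons)
  cfg$n_layers <- as.integer(n_layers)
  cfg$n_train_steps <- as.integer(n_train_steps)
  cfg$ramp_steps <- as.integer(n_train_steps %/% 4)
  cfg$n_runs <- as.integer(n_runs)
  cfg$velocities <- velocities
  validate_config(cfg)
  cfg
}

#' Read a configuration from a flat key/value file
#'
#' The file is YAML with scalar keys mirroring the [network_config()]
#' argument names (`velocities` may be a list). Keys that are absent take
#' their defaults, so an empty file yields the full default configuration.
#' Unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return An `stdpnet_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(network_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$velocities)) vals$velocities <- unlist(vals$velocities)
  do.call(network_config, vals)
}

#' Write a configuration to a YAML file
#'
#' @param config An `stdpnet_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  vals <- unclass(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}
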