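test_that("STDP kernel is zero at the origin, exponential on both sides, and antisymmetric when balanced", {
  cfg <- network_config()
  expect_identical(stdp_kernel(0, cfg), 0)
  expect_equal(stdp_kernel(20, cfg), exp(-1))
  expect_equal(stdp_kernel(-20, cfg), -exp(-1))
  dts <- seq(-140, 140, by = 0.5)
  expect_equal(stdp_kernel(dts, cfg), -stdp_kernel(-dts, cfg))
  # outside the window the kernel vanishes
  expect_identical(stdp_kernel(c(-141, 200), cfg), c(0, 0))
  # unbalanced parameters break antisymmetry in the expected direction
  cfg2 <- network_config(c_p = 2, c_d = 1)
  expect_equal(stdp_kernel(10, cfg2), 2 * exp(-0.5))
  expect_equal(stdp_kernel(-10, cfg2), -exp(-0.5))
})

test_that("learning rate ramps linearly over the first quarter then plateaus", {
  cfg <- network_config()
  expect_identical(learning_rate_at(0, cfg), 0)
  expect_equal(learning_rate_at(2500, cfg), 2e-4)
  expect_equal(learning_rate_at(5000, cfg), 4e-4)
  expect_equal(learning_rate_at(19999, cfg), 4e-4)
  expect_error(learning_rate_at(20000, cfg), "out of range")
  expect_error(learning_rate_at(-1, cfg), "out of range")
  # nondecreasing
  p <- learning_rate_at(seq(0, 19999, by = 97), cfg)
  expect_true(all(diff(p) >= 0))
})

test_that("normalization makes every incoming sum exactly one and is idempotent", {
  w <- manual_weights(3, list(cbind(c(1, 1, 2, 3), c(1, 2, 3, 1))),
                      list(c(0.2, 0.6, 2, 5)))
  n1 <- normalize_incoming(w)
  expect_equal(n1$blocks[[1]]$w, c(0.25, 0.75, 1, 1))
  expect_equal(incoming_sums(n1, 1)[1:3], c(1, 1, 1))
  n2 <- normalize_incoming(n1)
  expect_equal(n1$blocks[[1]]$w, n2$blocks[[1]]$w, tolerance = 1e-14)
  # zero incoming sum is an error naming the neuron
  w$blocks[[1]]$w <- c(0, 0, 1, 1)
  expect_error(normalize_incoming(w), "neuron 1 in layer 2")
})

test_that("the growth ceiling clamps at the per-block multiple of the max starting weight", {
  w <- manual_weights(3, list(cbind(c(1, 2, 3), c(1, 2, 3))),
                      list(c(0.01, 0.02, 0.05)))
  expect_equal(w$w_max_init, 0.05)
  w$blocks[[1]]$w <- c(0.01, 0.5, 0.1)   # 0.5 = 10x the max start
  capped <- apply_ceiling(w, factor = 3)
  expect_equal(capped$blocks[[1]]$w, c(0.01, 0.15, 0.1))
  # infinite factor is the identity
  same <- apply_ceiling(w, factor = Inf)
  expect_identical(same$blocks[[1]]$w, w$blocks[[1]]$w)
})

test_that("a pre spike arriving exactly with the post spike produces zero change", {
  cfg <- tiny_config(n_neurons = 4L, n_layers = 2L)
  w <- manual_weights(4, list(cbind(c(1, 1), c(1, 2))), list(c(0.5, 0.5)))
  hist <- new_spike_history(cfg)
  sp <- matrix(FALSE, 2, 4)
  # pre neuron 1 spikes at t = 0
  sp[1, 1] <- TRUE
  hist <- record_spikes(hist, sp, 0)
  w1 <- apply_stdp(w, hist, sp, 0, p_t = 0.1, cfg)
  # post spike at t = t_delay: effective difference 0, kernel 0
  sp2 <- matrix(FALSE, 2, 4); sp2[2, 1] <- TRUE
  hist <- record_spikes(hist, sp2, cfg$t_delay)
  w2 <- apply_stdp(w1, hist, sp2, cfg$t_delay, p_t = 0.1, cfg)
  expect_identical(w2$blocks[[1]]$w, c(0.5, 0.5))
  # no spikes anywhere leaves weights untouched
  w3 <- apply_stdp(w2, hist, matrix(FALSE, 2, 4), 40, 0.1, cfg)
  expect_identical(w3$blocks[[1]]$w, w2$blocks[[1]]$w)
})

test_that("incremental STDP equals the brute-force all-pairs oracle on random scripts", {
  cfg <- tiny_config(n_neurons = 5L, n_layers = 3L)
  cfg$lr_max <- 0.01
  edges <- list(cbind(c(1, 1, 2, 3, 4, 5), c(1, 2, 2, 3, 5, 4)),
                cbind(c(1, 2, 2, 4), c(2, 1, 3, 4)))
  set.seed(201)
  for (rep in 1:50) {
    w0 <- manual_weights(5, edges, list(runif(6, 5, 6), runif(4, 5, 6)),
                         n_layers = 3L)
    n_steps <- 60L
    raster <- random_raster(cfg, n_steps, p_spike = 0.10)
    # reference path: incremental updates with the spike-history buffer
    w_inc <- w0
    hist <- new_spike_history(cfg)
    for (s in 0:(n_steps - 1)) {
      t <- s * cfg$dt
      sp <- do.call(rbind, lapply(raster$per_layer, function(m)
        m[, s + 1] == 1))
      hist <- record_spikes(hist, sp, t)
      w_inc <- apply_stdp(w_inc, hist, sp, t, p_t = cfg$lr_max, cfg)
    }
    # independent oracle: direct enumeration of every spike pair
    w_or <- stdp_oracle(w0, raster$per_layer, cfg)
    expect_equal(flat_w(w_inc), flat_w(w_or), tolerance = 1e-12)
  }
})

test_that("the compiled engine's STDP matches the brute-force oracle on forced spike rasters", {
  cfg <- tiny_config(n_neurons = 6L, n_layers = 3L)
  cfg$norm_prob <- 0     # isolate the STDP pathway
  cfg$ramp_steps <- 40L  # exercise the ramp inside the window
  cfg$n_train_steps <- 2000L
  set.seed(202)
  g <- build_connectivity(cfg)
  for (rep in 1:10) {
    w0 <- init_weights(g, cfg)
    for (bi in seq_along(w0$blocks))
      w0$blocks[[bi]]$w <- runif(length(w0$blocks[[bi]]$w), 5, 6)
    w0$w_max_init <- vapply(w0$blocks, function(b) max(b$w), numeric(1))
    n_steps <- 80L
    raster <- random_raster(cfg, n_steps, p_spike = 0.12)
    res <- run_engine(w0, cfg, stim = NULL, n_steps = n_steps,
                      plastic = TRUE, forced_spikes = raster$forced)
    w_or <- stdp_oracle(w0, raster$per_layer, cfg,
                        lr = function(s) cfg$lr_max * min(1, s / cfg$ramp_steps))
    expect_equal(flat_w(res$weights), flat_w(w_or), tolerance = 1e-12)
  }
})

test_that("training is a no-op for the static network and under a zero learning rate", {
  set.seed(203)
  cfg <- tiny_config(n_neurons = 50L)
  g <- build_connectivity(cfg)
  # velocity 0: returned weights are freshly initialized, untrained
  w_static <- train_subpopulation(cfg, 0, graph = g)
  expect_false(w_static$trained)
  expect_equal(w_static$velocity, 0)
  sums <- incoming_sums(w_static, 1)
  expect_true(all(sums > 0))
  # sums are ~1 in expectation (fan-in varies at this tiny width)
  expect_equal(mean(sums), 1, tolerance = 0.15)
  # zero learning rate: engine returns the exact starting weights
  cfg0 <- cfg
  cfg0$lr_max <- 0
  cfg0$norm_prob <- 0
  w0 <- init_weights(g, cfg0)
  res <- run_engine(w0, cfg0, stimulus_moving(0.2, 0.5), n_steps = 300,
                    plastic = TRUE)
  expect_identical(flat_w(res$weights), flat_w(w0))
})

test_that("weights stay within [0, 3 x max starting weight] throughout training and sums return to one at each normalization", {
  set.seed(204)
  cfg <- tiny_config(n_neurons = 80L, n_layers = 3L)
  cfg$n_train_steps <- 1500L
  cfg$ramp_steps <- 300L
  g <- build_connectivity(cfg)
  w0 <- init_weights(g, cfg)
  res <- run_engine(w0, cfg, stimulus_moving(0.3, 0.5), n_steps = 1500,
                    plastic = TRUE, snapshot_every = 100L)
  expect_lte(res$max_ratio, 3 + 1e-12)
  expect_true(all(res$weights_flat >= 0))
  for (k in seq_along(res$snapshot_steps)) {
    wk <- stdpnet:::unflatten_weights(w0, res$snapshots[[k]])
    for (bi in seq_along(wk$blocks))
      expect_lte(max(wk$blocks[[bi]]$w), 3 * w0$w_max_init[bi] + 1e-12)
  }
  # a snapshot taken at a forced normalization event has unit sums
  cfg2 <- cfg
  cfg2$norm_prob <- 1   # normalize every step
  res2 <- run_engine(w0, cfg2, stimulus_moving(0.3, 0.5), n_steps = 50,
                     plastic = TRUE)
  wn <- res2$weights
  for (bi in seq_along(wn$blocks))
    expect_equal(max(abs(incoming_sums(wn, bi) - 1)), 0, tolerance = 1e-12)
})

test_that("balanced STDP with a stationary stimulus leaves receptive fields unshifted on average", {
  set.seed(205)
  cfg <- tiny_config(n_neurons = 120L, n_layers = 3L)
  cfg$n_train_steps <- 1500L
  cfg$ramp_steps <- 300L
  shifts <- replicate(10, {
    g <- build_connectivity(cfg)   # independent graphs across seeds
    un <- init_weights(g, cfg)
    res <- run_engine(un, cfg, stimulus_moving(runif(1), 0),
                      n_steps = cfg$n_train_steps, plastic = TRUE)
    measure_rf_shift(res$weights, un, 2, direction = 1,
                     kernel_sigma = cfg$kde_sigma)
  })
  se <- sd(shifts) / sqrt(length(shifts))
  expect_lt(abs(mean(shifts)), 2 * se + 1e-4)
})

test_that("receptive-field shift growth decelerates toward an asymptote during training", {
  set.seed(207)
  cfg <- reduced_profile(network_config(), n_neurons = 300L, n_layers = 2L,
                         n_train_steps = 100000L, n_runs = 1L)
  g <- build_connectivity(cfg)
  un <- init_weights(g, cfg)
  res <- run_engine(un, cfg, stimulus_moving(runif(1), 0.5),
                    n_steps = cfg$n_train_steps, plastic = TRUE,
                    snapshot_every = 25000L)
  shift_at <- vapply(seq_along(res$snapshot_steps), function(k) {
    wk <- stdpnet:::unflatten_weights(un, res$snapshots[[k]])
    measure_rf_shift(wk, un, 2, direction = 1, kernel_sigma = cfg$kde_sigma)
  }, numeric(1))
  # shift accumulates in one direction and its growth slows after the ramp:
  # the final quarter adds less than the second quarter
  expect_true(all(diff(shift_at) > 0))
  inc <- diff(shift_at)
  expect_lt(inc[3], inc[1])
})

test_that("training with rightward motion loads weight mass opposite to motion at layer 2", {
  set.seed(206)
  cfg <- reduced_profile(network_config(), n_neurons = 200L, n_layers = 3L,
                         n_train_steps = 2000L, n_runs = 1L)
  g <- build_connectivity(cfg)
  signs <- replicate(10, {
    un <- init_weights(g, cfg)
    res <- run_engine(un, cfg, stimulus_moving(runif(1), 0.5),
                      n_steps = cfg$n_train_steps, plastic = TRUE)
    tr <- res$weights
    # mass on the side opposite to motion minus mass along motion
    b <- tr$blocks[[1]]
    d <- circular_distance(neuron_positions(200)[b$pre],
                           neuron_positions(200)[b$post])
    sum(b$w[d < 0]) - sum(b$w[d > 0])
  })
  # one-sided sign test over the 10 seeds
  expect_gt(sum(signs > 0), 8)
})
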