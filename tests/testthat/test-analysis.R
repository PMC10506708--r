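test_that("wrapped-Gaussian KDE is unimodal on one sample, symmetric on two, and integrates to one", {
  p1 <- smooth_to_pdf(0.5, 1 / 32, 128)
  expect_equal(find_pdf_peak(p1), 0.5)
  expect_true(all(p1$density >= 0))
  expect_equal(mean(p1$density), 1, tolerance = 1e-9)  # unit circle integral
  p2 <- smooth_to_pdf(c(0, 0.5), 1 / 32, 128)
  expect_equal(p2$density[1], p2$density[65], tolerance = 1e-9)
  # two modes of equal height
  expect_equal(sort(order(p2$density, decreasing = TRUE)[1:2]), c(1, 65))
  expect_error(smooth_to_pdf(numeric(0), 1 / 32, 128), "empty")
})

test_that("KDE of a large wrapped-normal sample recovers its width by moments", {
  set.seed(301)
  sigma <- 0.05
  kern <- 0.01
  x <- (rnorm(20000, mean = 0.3, sd = sigma)) %% 1
  pdf <- smooth_to_pdf(x, kern, 400)
  R <- Mod(sum(pdf$density * exp(2i * pi * pdf$grid))) / sum(pdf$density)
  sigma_smooth <- sqrt(-2 * log(R)) / (2 * pi)
  sigma_hat <- sqrt(max(sigma_smooth^2 - kern^2, 0))
  expect_equal(sigma_hat, sigma, tolerance = 0.1)
})

test_that("peak finding breaks ties at the smallest index and is shift-equivariant", {
  uniform <- structure(list(grid = neuron_positions(50),
                            density = rep(1, 50)), class = "circular_pdf")
  expect_identical(find_pdf_peak(uniform), 0)
  pdf <- smooth_to_pdf(0.32, 1 / 32, 200)
  shift <- 37 / 200
  shifted <- structure(list(grid = pdf$grid,
                            density = pdf$density[((seq_len(200) - 1 - 37) %% 200) + 1]),
                       class = "circular_pdf")
  expect_equal(circular_distance(find_pdf_peak(shifted), find_pdf_peak(pdf)),
               shift, tolerance = 1e-12)
})

test_that("the grid peak and the circular-mean center agree for unimodal symmetric profiles", {
  for (ctr in c(0.1, 0.5, 0.93)) {
    pdf <- smooth_to_pdf(ctr, 1 / 32, 256)
    expect_lt(abs(circular_distance(find_pdf_peak(pdf),
                                    pdf_circular_mean(pdf))), 1 / 256)
  }
})

test_that("untrained mean receptive fields are centered at the reference position", {
  set.seed(302)
  cfg <- network_config(n_neurons = 300L, n_layers = 3L)
  g <- build_connectivity(cfg)
  w <- init_weights(g, cfg)
  for (l in 2:3) {
    rf <- mean_receptive_field(w, l, reference = 0.5)
    expect_lt(abs(circular_distance(pdf_circular_mean(rf), 0.5)), 1 / 300)
  }
  expect_error(mean_receptive_field(w, 1), "layer 1")
})

test_that("moving all weight mass one neuron leftward moves the mean receptive field by -1/N", {
  set.seed(303)
  cfg <- network_config(n_neurons = 100L, n_layers = 2L)
  g <- build_connectivity(cfg)
  w <- init_weights(g, cfg)
  n <- 100L
  w_shift <- w
  # reassign each weight to the presynaptic neuron one index lower
  w_shift$blocks[[1]]$pre <- ((w$blocks[[1]]$pre - 2L) %% n) + 1L
  rf0 <- mean_receptive_field(w, 2, reference = 0.5)
  rf1 <- mean_receptive_field(w_shift, 2, reference = 0.5)
  expect_equal(circular_distance(pdf_circular_mean(rf1),
                                 pdf_circular_mean(rf0)),
               -1 / n, tolerance = 1e-6)
})

test_that("receptive-field shift is zero for identical tensors and follows the sign convention for pure rotations", {
  set.seed(304)
  cfg <- network_config(n_neurons = 100L, n_layers = 2L)
  g <- build_connectivity(cfg)
  w <- init_weights(g, cfg)
  expect_equal(measure_rf_shift(w, w, 2, direction = 1), 0)
  # all-to-all graph with Gaussian weight profiles, so a pure receptive-field
  # rotation by -3/N (opposite to rightward motion) can share the graph:
  # reported shift is +3/N under the positive-opposite-to-motion convention
  n <- 60L
  pos <- neuron_positions(n)
  edges <- list(cbind(rep(1:n, each = n), rep(1:n, n)))
  d <- circular_distance(pos[edges[[1]][, 2]], pos[edges[[1]][, 1]])
  w_ctr <- manual_weights(n, edges, list(wrapped_gaussian(d, 0.05)))
  w_rot <- manual_weights(n, edges,
                          list(wrapped_gaussian(circular_distance(d, -3 / n),
                                                0.05)))
  expect_equal(measure_rf_shift(w_rot, w_ctr, 2, direction = 1), 3 / n,
               tolerance = 1e-6)
  # leftward motion flips the reported sign
  expect_equal(measure_rf_shift(w_rot, w_ctr, 2, direction = -1), -3 / n,
               tolerance = 1e-6)
  # mismatched graphs are refused
  set.seed(305)
  g2 <- build_connectivity(cfg)
  w2 <- init_weights(g2, cfg)
  expect_error(measure_rf_shift(w, w2, 2), "different connectivity")
})

test_that("untrained trained/untrained pairs show no systematic receptive-field shift", {
  set.seed(306)
  cfg <- network_config(n_neurons = 150L, n_layers = 2L)
  shifts <- replicate(10, {
    g <- build_connectivity(cfg)
    a <- init_weights(g, cfg)
    b <- init_weights(g, cfg)
    measure_rf_shift(a, b, 2, direction = 1)
  })
  se <- sd(shifts) / sqrt(length(shifts))
  expect_lt(abs(mean(shifts)), 2 * se + 1e-4)
})

test_that("von Mises fitting recovers parameters across a concentration grid", {
  set.seed(307)
  rvm <- function(n, mu, kappa) {
    # rejection sampler (Best-Fisher)
    out <- numeric(n); k <- 0
    a <- 1 + sqrt(1 + 4 * kappa^2); b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    while (k < n) {
      u <- runif(3)
      z <- cos(pi * u[1]); f <- (1 + r * z) / (r + z); c <- kappa * (r - f)
      if (c * (2 - c) - u[2] > 0 || log(c / u[2]) + 1 - c >= 0) {
        k <- k + 1
        out[k] <- (mu + sign(u[3] - 0.5) * acos(f))
      }
    }
    out
  }
  for (kappa in c(0.5, 2, 8)) {
    for (mu in c(-2, 0.3, 2.8)) {
      x <- rvm(10000, mu, kappa)
      fit <- fit_von_mises(x)
      se <- 1 / sqrt(fit$n * fit$R_bar * fit$kappa)
      expect_lt(abs(Arg(exp(1i * (fit$mu - mu)))), 3 * se + 0.02)
      expect_equal(fit$kappa, kappa, tolerance = 0.1)
    }
  }
  # degenerate cases
  all_same <- fit_von_mises(rep(1.2, 50))
  expect_equal(all_same$mu, 1.2)
  expect_equal(all_same$kappa, 1e4)
  sym <- fit_von_mises(c(0.7, -0.7))
  expect_equal(sym$mu, 0, tolerance = 1e-12)
  opposite <- fit_von_mises(c(0, pi))
  expect_true(is.na(opposite$mu))
  expect_identical(opposite$kappa, 0)
})

test_that("alignment score measures mean absolute deviation from the input layer", {
  expect_equal(alignment_score(rep(0.4, 5), 0.4), 0)
  expect_equal(alignment_score(rep(0.42, 5), 0.4), 0.02, tolerance = 1e-12)
  expect_equal(alignment_score(c(0.45, 0.35), 0.4), 0.05, tolerance = 1e-12)
  # wraps correctly across zero
  expect_equal(alignment_score(c(0.98), 0.02), 0.04, tolerance = 1e-12)
  expect_error(alignment_score(c(0.1, NA), 0.2), "missing")
  # rotation invariance
  set.seed(308)
  x <- runif(5); ref <- runif(1); delta <- runif(1)
  expect_equal(alignment_score(x, ref),
               alignment_score((x + delta) %% 1, (ref + delta) %% 1),
               tolerance = 1e-12)
})
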