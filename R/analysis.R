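#' Wrapped-Gaussian kernel density on the ring
#'
#' Smooths a (possibly weighted) sample of positions on `[0, 1)` with a
#' wrapped Gaussian kernel, evaluated on the uniform neuron-position grid,
#' and normalizes so the density integrates to 1 over the circle.
#'
#' @param samples Positions in cycles.
#' @param kernel_sigma Kernel width, cycles.
#' @param n_grid Number of grid points (use the layer's neuron count).
#' @param weights Optional nonnegative sample weights.
#' @return An object of class `circular_pdf`: list with `grid` (positions)
#'   and `density` (nonnegative, `mean(density) == 1` so the Riemann
#'   integral over the unit circle is 1).
#' @export
smooth_to_pdf <- function(samples, kernel_sigma, n_grid,
                          weights = NULL) {
  if (length(samples) == 0) stop("empty sample set")
  if (is.null(weights)) weights <- rep(1, length(samples))
  stopifnot(length(weights) == length(samples), all(weights >= 0))
  if (sum(weights) <= 0) stop("total sample weight must be positive")
  grid <- neuron_positions(n_grid)
  d <- outer(grid, samples, circular_distance)
  dens <- as.numeric(wrapped_gaussian(d, kernel_sigma) %*% weights)
  dens <- dens / mean(dens)  # integral over [0,1) on the uniform grid = 1
  structure(list(grid = grid, density = dens), class = "circular_pdf")
}

#' @export
print.circular_pdf <- function(x, ...) {
  cat(sprintf("<circular_pdf> %d grid points, peak %.4g at %.4f cycles\n",
              length(x$grid), max(x$density), find_pdf_peak(x)))
  invisible(x)
}

#' Peak position of a circular density
#'
#' Returns the grid position with maximal density. Ties are broken by the
#' smallest grid index (so a completely uniform density returns position 0).
#'
#' @param pdf A `circular_pdf`.
#' @return Position in cycles.
#' @export
find_pdf_peak <- function(pdf) {
  pdf$grid[which.max(pdf$density)]
}

#' Circular mean of a density
#'
#' First trigonometric moment of the density, mapped back to `[0, 1)`.
#' Used as the receptive-field "center", which is robust at grid
#' resolution; for unimodal near-symmetric profiles it agrees with
#' [find_pdf_peak()] to within one grid step.
#'
#' @param pdf A `circular_pdf`.
#' @return Position in cycles (NA if the resultant vanishes).
#' @export
pdf_circular_mean <- function(pdf) {
  circular_mean_positions(pdf$grid, pdf$density)
}

#' Mean receptive field of a layer
#'
#' Each neuron's incoming weight profile (weights laid out over the
#' presynaptic preferred positions, weight magnitude proportional to
#' probability density) is rotated so the neuron's own preferred position
#' maps to a common reference position, the rotated profiles are averaged
#' across the layer, and the average is smoothed with a wrapped Gaussian
#' kernel and renormalized.
#'
#' @param weights An `stdpnet_weights`.
#' @param layer Layer index, 2..n_layers (layer 1 has no incoming weights).
#' @param reference Reference position the receptive fields are aligned to,
#'   cycles.
#' @param kernel_sigma Smoothing width, cycles.
#' @return A `circular_pdf` over presynaptic position.
#' @export
mean_receptive_field <- function(weights, layer, reference = 0.5,
                                 kernel_sigma = 1 / 32) {
  if (layer < 2 || layer > weights$n_layers)
    stop("layer must be in 2..n_layers (layer 1 has no incoming weights)")
  b <- weights$blocks[[layer - 1L]]
  n <- weights$n_neurons
  ref_idx <- as.integer(round(reference * n))  # 0-based grid index
  # rotate each neuron's profile so its own index lands on the reference
  idx <- ((b$pre - b$post + ref_idx) %% n) + 1L
  acc <- rowsum_by(b$w, idx, n)
  smooth_to_pdf(neuron_positions(n), kernel_sigma, n, weights = acc)
}

#' Receptive-field shift between a trained and an untrained network
#'
#' Circular difference between the mean-receptive-field centers of the
#' trained and untrained weight tensors (which must share a connectivity
#' graph). The sign convention is positive when the shift is opposite to
#' the motion direction (the direction STDP is expected to shift receptive
#' fields).
#'
#' @param trained,untrained `stdpnet_weights` on the same graph.
#' @param layer Layer index >= 2.
#' @param direction Motion direction, `+1` (increasing position) or `-1`;
#'   defaults to the sign of the trained tensor's velocity (or +1).
#' @param kernel_sigma Smoothing width, cycles.
#' @return Shift in cycles (positive = opposite to motion).
#' @export
measure_rf_shift <- function(trained, untrained, layer, direction = NULL,
                             kernel_sigma = 1 / 32) {
  if (!same_graph(trained, untrained))
    stop("trained and untrained weights are on different connectivity graphs")
  if (is.null(direction)) {
    v <- trained$velocity
    direction <- if (!is.na(v) && v < 0) -1 else 1
  }
  ctr_tr <- pdf_circular_mean(mean_receptive_field(trained, layer,
                                                   kernel_sigma = kernel_sigma))
  ctr_un <- pdf_circular_mean(mean_receptive_field(untrained, layer,
                                                   kernel_sigma = kernel_sigma))
  -direction * circular_distance(ctr_tr, ctr_un)
}

#' Maximum-likelihood von Mises fit
#'
#' Fits mean direction and concentration to a sample of angles: `mu` is the
#' circular mean of the unit vectors and `kappa` inverts the mean resultant
#' length through the standard ratio-of-Bessel equation
#' `A1(kappa) = R_bar` (Best-Fisher approximation, refined by
#' Newton steps on `A1`). Degenerate samples with all angles equal drive
#' `kappa` to the cap of 1e4; a vanishing resultant leaves `mu` undefined
#' (`NA`) with `kappa = 0`.
#'
#' @param angles Angles in radians.
#' @return An object of class `von_mises_fit`: list with `mu` (radians in
#'   `[-pi, pi)`), `mu_cycles` (same direction in cycles, `[-0.5, 0.5)`),
#'   `kappa`, `R_bar` and `n`.
#' @export
fit_von_mises <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles")
  z <- mean(exp(1i * angles))
  R <- Mod(z)
  if (R < 1e-10) {
    fit <- list(mu = NA_real_, mu_cycles = NA_real_, kappa = 0,
                R_bar = R, n = n)
    class(fit) <- "von_mises_fit"
    return(fit)
  }
  mu <- Arg(z)  # in (-pi, pi]
  if (mu >= pi) mu <- mu - 2 * pi
  kappa <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  # refine by Newton on A1(kappa) - R = 0 (A1 = I1/I0)
  A1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  for (it in 1:25) {
    if (!is.finite(kappa) || kappa > 1e4) { kappa <- 1e4; break }
    a <- A1(kappa)
    deriv <- 1 - a / kappa - a^2
    if (deriv <= 0) break
    step <- (a - R) / deriv
    kappa_new <- kappa - step
    if (!is.finite(kappa_new) || kappa_new <= 0) { kappa <- kappa / 2; next }
    if (abs(kappa_new - kappa) < 1e-10 * (1 + kappa)) { kappa <- kappa_new; break }
    kappa <- kappa_new
  }
  kappa <- min(kappa, 1e4)
  fit <- list(mu = mu, mu_cycles = mu / (2 * pi), kappa = kappa,
              R_bar = R, n = n)
  class(fit) <- "von_mises_fit"
  fit
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf("<von_mises_fit> mu = %.4f rad (%.4f cycles), kappa = %.3g, n = %d\n",
              x$mu, x$mu_cycles, x$kappa, x$n))
  invisible(x)
}

#' Standard error of a von Mises mean direction
#'
#' Large-sample circular standard error `1 / sqrt(n * R_bar * kappa)`
#' (radians), with `Inf` for degenerate fits.
#'
#' @param fit A `von_mises_fit`.
#' @param cycles Return the error in cycles instead of radians.
#' @return Standard error of the mean direction.
#' @export
von_mises_se <- function(fit, cycles = FALSE) {
  if (fit$kappa <= 0 || fit$R_bar <= 0) return(Inf)
  se <- 1 / sqrt(fit$n * fit$R_bar * fit$kappa)
  if (cycles) se / (2 * pi) else se
}

#' Cross-layer alignment score
#'
#' Mean absolute circular deviation of the higher layers' represented
#' positions from the input layer's represented position at one timepoint.
#' Zero means all layers represent the same position (perfect realtime
#' alignment); larger values mean representations are spread apart.
#'
#' @param per_layer_positions Positions (cycles) for layers 2..n_layers, in
#'   layer order.
#' @param input_layer_position Position (cycles) for the input layer.
#' @return Nonnegative score in cycles.
#' @export
alignment_score <- function(per_layer_positions, input_layer_position) {
  if (any(!is.finite(c(per_layer_positions, input_layer_position))))
    stop("missing layer position")
  mean(abs(circular_distance(per_layer_positions, input_layer_position)))
}
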