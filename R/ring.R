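#' Signed circular distance on the unit ring
#'
#' Positions live on the circular interval `[0, 1)`. The signed distance
#' `a - b` is wrapped into the half-open interval `[-0.5, 0.5)`; the
#' antipodal case (distance exactly one half) returns `-0.5`.
#'
#' @param a,b Numeric vectors of positions in cycles (recycled).
#' @return Numeric vector of signed distances in `[-0.5, 0.5)`.
#' @examples
#' circular_distance(0.95, 0.05)  # -0.1, across the wrap
#' circular_distance(0.75, 0.25)  # -0.5, antipodal tie-break
#' @export
circular_distance <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  d <- (a - b + 0.5) %% 1
  d - 0.5
}

#' Wrapped Gaussian bump with unit peak
#'
#' Sum of Gaussian images at integer offsets `k = -1, 0, 1`. For the widths
#' used throughout (`sigma <= 1/8` or so) the three-term wrap equals the full
#' wrapped sum to machine precision, because distances are pre-wrapped into
#' `[-0.5, 0.5)`.
#'
#' @param d Signed circular distances in cycles.
#' @param sigma Width in cycles.
#' @return Values in `(0, 1]`, equal to 1 at `d = 0`.
#' @export
wrapped_gaussian <- function(d, sigma) {
  s2 <- 2 * sigma^2
  exp(-d^2 / s2) + exp(-(d - 1)^2 / s2) + exp(-(d + 1)^2 / s2)
}

#' Preferred positions of a layer's neurons
#'
#' Neuron `j` (1-based) is tuned to position `(j - 1) / n` on the ring.
#'
#' @param n Number of neurons in the layer.
#' @return Numeric vector of length `n`.
#' @export
neuron_positions <- function(n) {
  (seq_len(n) - 1) / n
}

# wrap an arbitrary position into [0, 1)
wrap_position <- function(x) {
  x %% 1
}

# circular mean of weighted positions (cycles), NA when the resultant vanishes
circular_mean_positions <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  z <- sum(w * exp(2i * pi * x))
  if (Mod(z) / sum(w) < 1e-12) return(NA_real_)
  wrap_position(Arg(z) / (2 * pi))
}
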