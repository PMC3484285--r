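#' Closed-form grid field spacing
#'
#' Spacing between neighbouring vertices of the hexagonal firing grid
#' produced by the oscillatory-interference model:
#' `G = 2 / (sqrt(3) * beta * f)`. With the defaults (f = 7.38 Hz,
#' beta = 0.00385 s/cm) G is about 41 cm.
#'
#' @param f Somatic frequency, Hz.
#' @param beta Velocity gain, s/cm.
#' @return Grid spacing in cm.
#' @export
grid_spacing <- function(f, beta) {
  if (any(f <= 0) || any(beta <= 0)) stop("f and beta must be positive")
  2 / (sqrt(3) * beta * f)
}

#' Closed-form inter-band distance
#'
#' Band spacing of a single velocity-modulated dendritic oscillation:
#' `L = 1 / (beta * f)`; the hexagonal grid spacing is `G = 2 L / sqrt(3)`.
#'
#' @inheritParams grid_spacing
#' @return Band distance in cm.
#' @export
band_distance <- function(f, beta) {
  if (any(f <= 0) || any(beta <= 0)) stop("f and beta must be positive")
  1 / (beta * f)
}

#' Simulate grid-cell spiking with the oscillatory-interference model
#'
#' Three dendritic oscillations, one per basis vector `b_k`, are phase
#' advanced by `omega * beta * I_k(t)` where `I_k` is the integral of the
#' planar velocity projected on `b_k` — equivalently the displacement of
#' the (integrated) path from its start along `b_k`. A spike is emitted at
#' a sample when the product of the three interference pairs
#' `cos(omega t) + cos(omega t + omega beta I_k)` exceeds the threshold.
#' The product is evaluated at the trajectory rate; `oversample` evaluates
#' the oscillators on a finer time base and spikes if any sub-sample
#' crosses the threshold.
#'
#' @param path A `"path_state"` (or any data frame with `t`, `x`, `y`):
#'   the path whose displacements drive the dendritic phases.
#' @param params An [oscillator_params()].
#' @param positions Optional [position_series()] at which spikes are
#'   registered (defaults to the driving path itself). Use the ground-truth
#'   trajectory here to see how integration errors deform the spatial
#'   firing pattern.
#' @param oversample Integer oscillator evaluations per trajectory sample.
#' @return An object of class `"spike_train"`: data frame `t`, `x`, `y`
#'   (registration positions), `spike` (0/1), with `dt` as an attribute.
#' @export
simulate_grid_cell <- function(path, params = oscillator_params(),
                               positions = NULL, oversample = 1) {
  if (is.null(positions)) positions <- path
  stopifnot(nrow(positions) == nrow(path), oversample >= 1)
  tt <- path$t
  w <- 2 * pi * params$f
  ang <- deg2rad(params$basis_angles)
  ## displacement integrals: int v2d . b_k ds = (p(t) - p(0)) . b_k
  dx <- path$x - path$x[1]
  dy <- path$y - path$y[1]
  prod_at <- function(tv, dxv, dyv) {
    p <- rep(1, length(tv))
    for (k in 1:3) {
      I_k <- dxv * cos(ang[k]) + dyv * sin(ang[k])
      p <- p * (cos(w * tv) + cos(w * tv + w * params$beta * I_k))
    }
    p
  }
  if (oversample == 1) {
    spike <- as.integer(prod_at(tt, dx, dy) > params$theta_spike)
  } else {
    n <- length(tt)
    spike <- integer(n)
    dt <- if (n > 1) tt[2] - tt[1] else 0.02
    for (j in seq_len(oversample)) {
      frac <- (j - 1) / oversample
      ts <- tt + frac * dt
      ## hold displacement constant within a sample
      spike <- pmax(spike,
                    as.integer(prod_at(ts, dx, dy) > params$theta_spike))
    }
  }
  out <- data.frame(t = tt, x = positions$x, y = positions$y,
                    spike = spike)
  class(out) <- c("spike_train", "data.frame")
  attr(out, "dt") <- if (length(tt) > 1) tt[2] - tt[1] else NA_real_
  attr(out, "params") <- params
  out
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d samples, %d spikes (%.2f Hz)\n",
              nrow(x), sum(x$spike),
              sum(x$spike) / (nrow(x) * attr(x, "dt"))))
  invisible(x)
}

#' Spike positions of a spike train
#'
#' @param spikes A `"spike_train"`.
#' @return Two-column matrix of the positions at which spikes occurred.
#' @export
spike_positions <- function(spikes) {
  cbind(x = spikes$x[spikes$spike == 1], y = spikes$y[spikes$spike == 1])
}
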