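# shared fixtures built in code

# grid with pixel centres at exactly the angles given
exact_grid <- function(theta, phi, cam = camera_config()) {
  g <- expand.grid(theta = theta, phi = phi)
  structure(list(theta = g$theta, phi = g$phi, n_az = length(theta),
                 n_el = length(phi), cam = cam),
            class = "sensor_grid")
}

# straight constant-speed run along +x, already clean
straight_run <- function(n = 100, speed = 10, rate = 50) {
  dt <- 1 / rate
  position_series(t = dt * (0:(n - 1)), x = speed * dt * (0:(n - 1)),
                  y = rep(0, n))
}

# smooth path plus stationary jitter clusters (sub-threshold steps) that
# the cleaning rules are expected to remove
jittered_walk <- function(seed = 1, n = 300) {
  set.seed(seed)
  dt <- 0.02
  phi <- cumsum(rnorm(n, 0, 4))
  v <- runif(n, 5, 30)
  x <- cumsum(v * dt * cos(phi * pi / 180))
  y <- cumsum(v * dt * sin(phi * pi / 180))
  # insert a stationary cluster in the middle
  xi <- c(x[1:150], x[150] + cumsum(runif(20, 0.005, 0.04)) * 0,
          x[151:n])
  yi <- c(y[1:150], y[150] + runif(20, -0.02, 0.02), y[151:n])
  position_series(t = dt * (seq_along(xi) - 1), x = xi, y = yi)
}

# ideal hexagonal rate map: Gaussian bumps on a triangular lattice
hex_rate_map <- function(spacing = 40, extent = 85, n_bins = 121,
                         sigma = 6) {
  centers <- seq(-extent, extent, length.out = n_bins)
  pts <- expand.grid(i = -6:6, j = -6:6)
  vx <- c(spacing, 0)
  vy <- c(spacing / 2, spacing * sqrt(3) / 2)
  px <- pts$i * vx[1] + pts$j * vy[1]
  py <- pts$i * vx[2] + pts$j * vy[2]
  keep <- px^2 + py^2 <= (extent * 1.4)^2
  px <- px[keep]; py <- py[keep]
  rate <- matrix(0, n_bins, n_bins)
  for (k in seq_along(px))
    rate <- rate + outer(exp(-(centers - px[k])^2 / (2 * sigma^2)),
                         exp(-(centers - py[k])^2 / (2 * sigma^2)))
  structure(list(rate = rate, spikes = rate, occupancy = rate * 0 + 1,
                 smoothed_occupancy = rate * 0 + 1,
                 visited = rate > -1, centers = centers,
                 bin_size = diff(centers)[1]),
            class = "rate_map")
}

# square-lattice analogue
square_rate_map <- function(spacing = 40, extent = 85, n_bins = 121,
                            sigma = 6) {
  centers <- seq(-extent, extent, length.out = n_bins)
  pts <- expand.grid(px = spacing * (-4:4), py = spacing * (-4:4))
  rate <- matrix(0, n_bins, n_bins)
  for (k in seq_len(nrow(pts)))
    rate <- rate + outer(exp(-(centers - pts$px[k])^2 / (2 * sigma^2)),
                         exp(-(centers - pts$py[k])^2 / (2 * sigma^2)))
  structure(list(rate = rate, spikes = rate, occupancy = rate * 0 + 1,
                 smoothed_occupancy = rate * 0 + 1,
                 visited = rate > -1, centers = centers,
                 bin_size = diff(centers)[1]),
            class = "rate_map")
}

# concentric-ring (rotationally symmetric) map
ring_rate_map <- function(extent = 85, n_bins = 121, period = 30) {
  centers <- seq(-extent, extent, length.out = n_bins)
  rr <- sqrt(outer(centers^2, centers^2, "+"))
  rate <- 1 + cos(2 * pi * rr / period)
  structure(list(rate = rate, spikes = rate, occupancy = rate * 0 + 1,
                 smoothed_occupancy = rate * 0 + 1,
                 visited = rate > -1, centers = centers,
                 bin_size = diff(centers)[1]),
            class = "rate_map")
}

# serpentine sweep covering a square region, for oscillator spacing tests
serpentine_path <- function(extent = 70, lane = 4, speed = 40, rate = 50) {
  dt <- 1 / rate
  ys <- seq(-extent, extent, by = lane)
  xs <- list()
  dir <- 1
  for (y in ys) {
    xr <- seq(-extent * dir, extent * dir, by = dir * speed * dt)
    xs[[length(xs) + 1]] <- cbind(xr, y)
    dir <- -dir
  }
  m <- do.call(rbind, xs)
  data.frame(t = dt * (seq_len(nrow(m)) - 1), x = m[, 1], y = m[, 2])
}
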