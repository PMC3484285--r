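#' Time-stamped position series
#'
#' Container for a 2-D trajectory sampled at a nominal rate (default 50 Hz):
#' a data frame with columns `t` (s), `x`, `y` (cm, arena frame with the
#' origin at the arena centre).
#'
#' @param t,x,y Numeric vectors of equal length.
#' @param arena Optional [arena_config()] the series belongs to.
#' @return An object of class `"position_series"` (a data frame).
#' @export
position_series <- function(t, x, y, arena = NULL) {
  stopifnot(length(t) == length(x), length(x) == length(y))
  if (anyNA(t) || anyNA(x) || anyNA(y))
    stop("position series must not contain missing values")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  out <- data.frame(t = t, x = x, y = y)
  class(out) <- c("position_series", "data.frame")
  attr(out, "arena") <- arena
  out
}

#' @export
print.position_series <- function(x, ...) {
  dur <- if (nrow(x) > 1) diff(range(x$t)) else 0
  cat(sprintf("<position_series> %d samples, %.1f s, max radius %.1f cm\n",
              nrow(x), dur, max(sqrt(x$x^2 + x$y^2))))
  invisible(x)
}

step_lengths <- function(x, y) sqrt(diff(x)^2 + diff(y)^2)

segment_headings <- function(x, y) rad2deg(atan2(diff(y), diff(x)))

#' Clean a tracked trajectory with the three-rule iterative method
#'
#' Tracked head positions contain jitter and head turns that do not reflect
#' body motion. Cleaning applies three rules per pass until a fixpoint (or
#' `max_iter` passes): (1) insert a linearly interpolated midpoint between
#' the two samples around a heading change above `max_turn_per_step`;
#' (2) remove a sample whose displacement from its predecessor is below
#' `min_step` (the animal is considered stationary); (3) insert a midpoint
#' inside any step longer than `max_step`. Within a pass the rules are
#' applied in this order, front to back. Timestamps are regularised to the
#' nominal rate afterwards.
#'
#' @param raw A [position_series()] with at least 3 samples.
#' @param cfg A [preprocess_config()].
#' @param max_iter Maximum number of passes (default 10); a warning is
#'   emitted if the rules still fire afterwards.
#' @return A cleaned `position_series`; attributes `changed_fraction`
#'   (fraction of output points that were inserted or survived a
#'   neighbourhood edit relative to the raw count) and `iterations`.
#' @export
preprocess_trajectory <- function(raw, cfg = preprocess_config(),
                                  max_iter = 10) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (nrow(raw) < 3) stop("need at least 3 samples to clean a trajectory")
  if (any(diff(raw$t) <= 0)) stop("timestamps must be strictly increasing")
  x <- raw$x; y <- raw$y
  n_raw <- length(x)
  n_changed <- 0L
  it <- 0L

  insert_midpoints <- function(x, y, seg) {
    ## split segments seg (indices into steps); back to front so earlier
    ## indices stay valid
    for (s in sort(seg, decreasing = TRUE)) {
      x <- append(x, (x[s] + x[s + 1L]) / 2, after = s)
      y <- append(y, (y[s] + y[s + 1L]) / 2, after = s)
    }
    list(x = x, y = y)
  }

  repeat {
    it <- it + 1L
    changed <- FALSE

    ## rule 1: insert a midpoint in the segment leaving each sharp-turn
    ## vertex (heading change above the per-step threshold)
    h <- segment_headings(x, y)
    if (length(h) > 1) {
      turn <- abs(wrap180(diff(h)))                 # vertex at sample i+1
      bad <- which(turn > cfg$max_turn_per_step)
      if (length(bad)) {
        xy <- insert_midpoints(x, y, bad + 1L)      # split outgoing segment
        x <- xy$x; y <- xy$y
        n_changed <- n_changed + length(bad)
        changed <- TRUE
      }
    }

    ## rule 2: greedy front-to-back removal of sub-threshold displacements
    d <- step_lengths(x, y)
    if (any(d < cfg$min_step)) {
      keep <- logical(length(x)); keep[1] <- TRUE
      last <- 1L
      for (i in 2:length(x)) {
        if (sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2) >= cfg$min_step) {
          keep[i] <- TRUE; last <- i
        }
      }
      keep[length(x)] <- keep[length(x)] || sum(keep) < 3L
      n_changed <- n_changed + sum(!keep)
      x <- x[keep]; y <- y[keep]
      changed <- TRUE
    }

    ## rule 3: insert midpoints inside over-long steps
    d <- step_lengths(x, y)
    bad <- which(d > cfg$max_step)
    if (length(bad)) {
      xy <- insert_midpoints(x, y, bad)
      x <- xy$x; y <- xy$y
      n_changed <- n_changed + length(bad)
      changed <- TRUE
    }

    if (!changed || it >= max_iter) break
  }
  ## convergence check
  h <- segment_headings(x, y)
  d <- step_lengths(x, y)
  if (length(h) > 1 && (any(abs(wrap180(diff(h))) > cfg$max_turn_per_step) ||
                        any(d < cfg$min_step) || any(d > cfg$max_step)))
    warning("trajectory cleaning did not converge within the iteration cap")
  dt <- 1 / cfg$sample_rate
  out <- position_series(t = raw$t[1] + dt * (seq_along(x) - 1), x = x, y = y,
                         arena = attr(raw, "arena"))
  attr(out, "changed_fraction") <- n_changed / n_raw
  attr(out, "iterations") <- it
  out
}

#' Derive linear and rotational velocities from a cleaned trajectory
#'
#' Assumes the animal moves tangent to its trajectory: the heading at sample
#' i is the direction of the segment i -> i+1 (the final sample inherits the
#' previous heading). Linear speed is the step length times the sampling
#' rate; rotational velocity is the wrapped heading difference times the
#' rate.
#'
#' @param traj A [position_series()].
#' @return A data frame of class `"velocity_series"` with columns `t`,
#'   `v_z` (cm/s), `omega_y` (deg/s) and `phi_hd` (allocentric heading,
#'   degrees); same number of rows as `traj`.
#' @export
derive_velocities <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop("need at least 2 samples")
  dt <- diff(traj$t)
  h <- segment_headings(traj$x, traj$y)          # length n-1
  v <- step_lengths(traj$x, traj$y) / dt         # length n-1
  om <- if (n > 2) wrap180(diff(h)) / dt[-1] else 0  # length n-2
  om <- c(om, om[length(om)])                    # length n-1
  out <- data.frame(t = traj$t,
                    v_z = c(v, v[n - 1]),
                    omega_y = c(om, om[n - 1]),
                    phi_hd = c(h, h[n - 1]))
  class(out) <- c("velocity_series", "data.frame")
  out
}

#' Generate a synthetic foraging trajectory
#'
#' Emulates the movement statistics of a rat foraging on a circular
#' platform: 50 Hz sampling, a right-skewed speed distribution with its mode
#' near 10 cm/s tailing off toward 50 cm/s, smooth autocorrelated heading
#' changes, and a turning bias away from the boundary that keeps the animal
#' inside the recorded radius. Speeds are clipped to [2.5, 60] cm/s and
#' per-step turns are bounded so the result is a fixpoint of the cleaning
#' rules.
#'
#' @param duration Duration in seconds.
#' @param arena An [arena_config()].
#' @param seed Optional integer seed (reproducible output for equal seeds).
#' @param sample_rate Sampling rate, Hz.
#' @param speed_shape,speed_scale Gamma marginal for speed; the defaults
#'   (shape 3, scale 5) put the mode at 10 cm/s and the mean at 15 cm/s.
#' @param speed_ar,turn_ar Lag-1 autocorrelation of the latent speed process
#'   and of the turning-rate process.
#' @param turn_sd Stationary standard deviation of the turning rate, deg/s.
#' @param wall_margin Distance from the boundary (cm) at which the
#'   wall-avoidance turn bias activates.
#' @return A [position_series()].
#' @export
generate_synthetic_trajectory <- function(duration, arena = arena_config(),
                                          seed = NULL, sample_rate = 50,
                                          speed_shape = 3, speed_scale = 5,
                                          speed_ar = 0.995, turn_ar = 0.97,
                                          turn_sd = 40, wall_margin = 10) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sample_rate)
  dt <- 1 / sample_rate
  R <- arena$recorded_radius

  ## latent AR(1) -> gamma marginal for speed
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n) * sqrt(1 - speed_ar^2)
  for (i in 2:n) z[i] <- speed_ar * z[i - 1] + innov[i]
  v <- stats::qgamma(stats::pnorm(z), shape = speed_shape,
                     scale = speed_scale)
  v <- pmin(pmax(v, 2.5), 60)

  ## autocorrelated turning rate (deg/s)
  u <- numeric(n)
  u[1] <- stats::rnorm(1, 0, turn_sd)
  tin <- stats::rnorm(n, 0, turn_sd) * sqrt(1 - turn_ar^2)

  x <- numeric(n); y <- numeric(n)
  ## random interior start pointing inward-ish
  r0 <- 0.5 * R * sqrt(stats::runif(1)); a0 <- stats::runif(1, 0, 360)
  x[1] <- r0 * cos(deg2rad(a0)); y[1] <- r0 * sin(deg2rad(a0))
  phi <- stats::runif(1, 0, 360)
  max_turn_step <- 80 * dt * sample_rate   # deg per step, below the 90 limit

  for (i in 2:n) {
    u[i] <- turn_ar * u[i - 1] + tin[i]
    turn <- u[i] * dt
    ## wall avoidance: steer toward the centre when close to the boundary
    r <- sqrt(x[i - 1]^2 + y[i - 1]^2)
    if (R - r < wall_margin) {
      inward <- rad2deg(atan2(-y[i - 1], -x[i - 1]))
      off <- wrap180(inward - phi)
      gain <- (1 - (R - r) / wall_margin)
      turn <- turn + gain * 0.35 * off
    }
    turn <- max(min(turn, max_turn_step), -max_turn_step)
    phi <- phi + turn
    step <- v[i] * dt
    xn <- x[i - 1] + step * cos(deg2rad(phi))
    yn <- y[i - 1] + step * sin(deg2rad(phi))
    k <- 0L
    while (xn^2 + yn^2 > R^2 && k < 12L) {
      ## turn harder toward the centre, keep the step length
      inward <- rad2deg(atan2(-y[i - 1], -x[i - 1]))
      phi <- phi + max(min(wrap180(inward - phi), max_turn_step),
                       -max_turn_step)
      xn <- x[i - 1] + step * cos(deg2rad(phi))
      yn <- y[i - 1] + step * sin(deg2rad(phi))
      k <- k + 1L
    }
    if (xn^2 + yn^2 > R^2) {            # pathological corner: shrink step
      sc <- 0.999 * R / sqrt(xn^2 + yn^2)
      xn <- xn * sc; yn <- yn * sc
    }
    x[i] <- xn; y[i] <- yn
  }
  position_series(t = dt * (seq_len(n) - 1), x = x, y = y, arena = arena)
}

#' Read / write trajectories as delimited text
#'
#' Files hold columns time (s), x (cm), y (cm), whitespace- or
#' comma-delimited, optionally with a header line. `NaN`/`NA` tokens are
#' accepted on read; the longest contiguous run of rows free of missing
#' values is returned. Malformed rows raise an error that reports their line
#' numbers.
#'
#' @param file Path to the file.
#' @return A [position_series()].
#' @export
read_trajectory <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trajectory file: ", file)
  first <- strsplit(trimws(lines[1]), "[,[:space:]]+")[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(first[1])))
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) stop("empty trajectory file: ", file)
  rows <- strsplit(trimws(lines[start:length(lines)]), "[,[:space:]]+")
  bad <- which(vapply(rows, length, 1L) != 3L)
  if (length(bad))
    stop("malformed rows (expected 3 columns) at lines: ",
         paste(bad + start - 1L, collapse = ", "))
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 3,
              byrow = TRUE)
  ok <- stats::complete.cases(m) & is.finite(m[, 1])
  if (!any(ok)) stop("no complete rows in trajectory file: ", file)
  ## longest run of complete rows
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- (ends[best] - r$lengths[best] + 1L):ends[best]
  position_series(t = m[idx, 1], x = m[idx, 2], y = m[idx, 3])
}

#' @rdname read_trajectory
#' @param traj A [position_series()] to write.
#' @param digits Number of significant digits retained.
#' @export
write_trajectory <- function(traj, file, digits = 10) {
  df <- data.frame(t = signif(traj$t, digits), x = signif(traj$x, digits),
                   y = signif(traj$y, digits))
  utils::write.table(df, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
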