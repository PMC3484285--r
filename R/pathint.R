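#' Decode self-motion along a whole trajectory
#'
#' Fast path over all frames of a trajectory: for each sample the analytic
#' curvilinear flow field is ray-traced against the platform disc, corrupted
#' with Gaussian noise, and decoded with the two-stage template match. The
#' per-frame computation is identical to
#' [image_motion_curvilinear()] + [add_flow_noise()] +
#' [estimate_self_motion()] but runs in compiled code. Noise draws come from
#' the current R RNG stream, so results are reproducible under
#' [set.seed()].
#'
#' @param vel A [derive_velocities()] result (ground-truth velocities and
#'   headings).
#' @param traj The matching [position_series()].
#' @param bank A [template_bank()].
#' @param arena An [arena_config()].
#' @param sigma_flow Flow noise standard deviation.
#' @param method Readout method, see [readout_velocity()].
#' @param window_fraction Local vector sum window fraction.
#' @return A data frame with columns `v_hat`, `omega_hat`, `certainty_v`,
#'   `certainty_omega`, `n_valid`, one row per trajectory sample.
#' @export
estimate_self_motion_series <- function(vel, traj, bank,
                                        arena = arena_config(),
                                        sigma_flow = 0,
                                        method = "local_vector_sum",
                                        window_fraction = 0.02) {
  stopifnot(nrow(vel) == nrow(traj))
  m <- match(method, c("max", "vector_sum", "local_vector_sum")) - 1L
  if (is.na(m)) stop("unknown readout method: ", method)
  cam <- bank$cam
  res <- fg_estimate_series(traj$x, traj$y, vel$phi_hd, vel$v_z,
                            vel$omega_y, bank$grid$theta, bank$grid$phi,
                            cam$h, cam$gamma, arena$platform_radius,
                            cam$D_min, cam$D_max, sigma_flow,
                            bank$v_samples, bank$omega_samples,
                            bank$sigma_v, bank$sigma_omega, m,
                            window_fraction)
  if (anyNA(res$v_hat))
    stop("frames with zero valid flow pixels encountered")
  as.data.frame(res)
}

#' Integrate estimated velocities into a path
#'
#' Forward-Euler dead reckoning at the trajectory rate: the position
#' advances along the current heading with the current speed, then the
#' heading advances with the current rotational velocity, so that feeding
#' the velocities derived from a trajectory reproduces that trajectory
#' exactly.
#'
#' @param v_hat Linear speeds, cm/s.
#' @param omega_hat Rotational velocities, deg/s.
#' @param phi0 Initial heading, degrees.
#' @param p0 Initial position, length-2, cm.
#' @param dt Time step, s.
#' @return An object of class `"path_state"`: data frame `t`, `x`, `y`,
#'   `phi` (heading wrapped to (-180, 180]) with the input velocities kept
#'   as attributes.
#' @export
integrate_path <- function(v_hat, omega_hat, phi0, p0, dt = 0.02) {
  n <- length(v_hat)
  stopifnot(length(omega_hat) == n, n >= 1)
  x <- numeric(n); y <- numeric(n); phi <- numeric(n)
  x[1] <- p0[1]; y[1] <- p0[2]; phi[1] <- phi0
  if (n > 1) for (i in 1:(n - 1)) {
    x[i + 1] <- x[i] + v_hat[i] * dt * cos(deg2rad(phi[i]))
    y[i + 1] <- y[i] + v_hat[i] * dt * sin(deg2rad(phi[i]))
    phi[i + 1] <- phi[i] + omega_hat[i] * dt
  }
  out <- data.frame(t = dt * (seq_len(n) - 1), x = x, y = y,
                    phi = wrap180(phi))
  class(out) <- c("path_state", "data.frame")
  attr(out, "v_hat") <- v_hat
  attr(out, "omega_hat") <- omega_hat
  attr(out, "dt") <- dt
  out
}

#' Periodically reset an integrated path to ground truth
#'
#' Re-integrates the estimated velocities, replacing position and
#' orientation with their ground-truth values at every multiple of the
#' reset period, a stand-in for the non-flow cues (landmarks, vestibular
#' input) that would correct accumulated path-integration error.
#'
#' @param est A `"path_state"` from [integrate_path()] (its velocity
#'   attributes are re-integrated).
#' @param truth_traj Ground-truth [position_series()].
#' @param truth_heading Ground-truth headings, degrees (e.g.
#'   `derive_velocities(truth_traj)$phi_hd`).
#' @param cfg A [reset_config()].
#' @return A `"path_state"` with the corrected trajectory.
#' @export
apply_reset <- function(est, truth_traj, truth_heading,
                        cfg = reset_config()) {
  if (!is.finite(cfg$t_reset)) return(est)
  dt <- attr(est, "dt")
  v <- attr(est, "v_hat"); w <- attr(est, "omega_hat")
  n <- nrow(est)
  stopifnot(nrow(truth_traj) == n, length(truth_heading) == n)
  period <- max(1L, round(cfg$t_reset * 60 / dt))
  x <- numeric(n); y <- numeric(n); phi <- numeric(n)
  x[1] <- est$x[1]; y[1] <- est$y[1]; phi[1] <- est$phi[1]
  if (n > 1) for (i in 1:(n - 1)) {
    x[i + 1] <- x[i] + v[i] * dt * cos(deg2rad(phi[i]))
    y[i + 1] <- y[i] + v[i] * dt * sin(deg2rad(phi[i]))
    phi[i + 1] <- phi[i] + w[i] * dt
    if ((i + 1L) %% period == 0L) {        # samples period, 2*period, ...
      x[i + 1] <- truth_traj$x[i + 1]
      y[i + 1] <- truth_traj$y[i + 1]
      phi[i + 1] <- truth_heading[i + 1]
    }
  }
  out <- data.frame(t = est$t, x = x, y = y, phi = wrap180(phi))
  class(out) <- c("path_state", "data.frame")
  attr(out, "v_hat") <- v
  attr(out, "omega_hat") <- w
  attr(out, "dt") <- dt
  attr(out, "reset_period") <- period
  out
}

#' Position-error statistics between an integrated and a true path
#'
#' Per-sample Euclidean distance, and an angle error defined as the
#' absolute wrapped difference between the bearings of the true and
#' estimated positions seen from the arena centre (`angle = "bearing"`,
#' the default) or between true and integrated headings
#' (`angle = "heading"`).
#'
#' @param est A `"path_state"`.
#' @param truth_traj Ground-truth [position_series()].
#' @param truth_heading Ground-truth headings (needed for
#'   `angle = "heading"`).
#' @param angle Angle-error definition.
#' @return A list with `distance` and `angle` per-sample series and their
#'   means `mean_distance`, `mean_angle`.
#' @export
position_error_stats <- function(est, truth_traj, truth_heading = NULL,
                                 angle = c("bearing", "heading")) {
  angle <- match.arg(angle)
  stopifnot(nrow(est) == nrow(truth_traj))
  d <- sqrt((est$x - truth_traj$x)^2 + (est$y - truth_traj$y)^2)
  if (angle == "bearing") {
    a_true <- rad2deg(atan2(truth_traj$y, truth_traj$x))
    a_est <- rad2deg(atan2(est$y, est$x))
    ang <- abs(wrap180(a_true - a_est))
  } else {
    if (is.null(truth_heading)) stop("truth_heading required")
    ang <- abs(wrap180(truth_heading - est$phi))
  }
  list(distance = d, angle = ang,
       mean_distance = mean(d), mean_angle = mean(ang))
}
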