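#' Arena geometry
#'
#' The recording arena is a circular platform. The simulated ground platform
#' extends beyond the recorded cage radius so that a camera sitting at the
#' cage boundary and looking outward still receives flow from textured
#' ground.
#'
#' @param recorded_radius Radius of the recorded cage in cm (default 85).
#' @param platform_radius Radius of the simulated ground platform in cm
#'   (default 100, i.e. a 15 cm annulus around the cage).
#' @return An object of class `"arena_config"`.
#' @export
arena_config <- function(recorded_radius = 85, platform_radius = 100) {
  stopifnot(recorded_radius > 0, platform_radius >= recorded_radius)
  structure(list(recorded_radius = recorded_radius,
                 platform_radius = platform_radius),
            class = "arena_config")
}

#' Trajectory cleaning thresholds
#'
#' Thresholds for the three-rule iterative cleaning of tracked positions:
#' insert a midpoint where the heading turns by more than `max_turn_per_step`
#' between consecutive segments, drop a sample whose displacement from its
#' predecessor is below `min_step`, and insert a midpoint where the
#' displacement exceeds `max_step`. At 50 Hz the defaults correspond to
#' 4500 deg/s, 2.5 cm/s and 60 cm/s.
#'
#' @param max_turn_per_step Maximum heading change per step, degrees.
#' @param min_step Minimum displacement per step, cm.
#' @param max_step Maximum displacement per step, cm.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(max_turn_per_step = 90, min_step = 0.05,
                              max_step = 1.2, sample_rate = 50) {
  stopifnot(max_turn_per_step > 0, min_step > 0, max_step > min_step,
            sample_rate > 0)
  structure(list(max_turn_per_step = max_turn_per_step, min_step = min_step,
                 max_step = max_step, sample_rate = sample_rate),
            class = "preprocess_config")
}

#' Spherical camera configuration
#'
#' The camera is a spherical projection centred at the nodal point, mounted
#' at height `h` above the ground with its optical axis pitched by the tilt
#' angle `gamma` (positive tilts point the camera downward). Pixels form a
#' regular azimuth x elevation lattice spanning `+/-fov_az` horizontally and
#' `+/-fov_el` vertically; the defaults give the 40 x 20 = 800 pixel layout.
#'
#' @param h Eye height above ground, cm.
#' @param gamma Tilt of the optical axis, degrees (positive = downward).
#' @param fov_az Horizontal half field of view, degrees.
#' @param fov_el Vertical half field of view, degrees.
#' @param n_az Number of azimuth samples.
#' @param n_el Number of elevation samples.
#' @param D_min,D_max Valid depth range along a ray, cm.
#' @return An object of class `"camera_config"`.
#' @export
camera_config <- function(h = 3.5, gamma = 0, fov_az = 120, fov_el = 60,
                          n_az = 40, n_el = 20, D_min = 0, D_max = 1000) {
  stopifnot(h > 0, fov_az > 0, fov_el > 0, n_az >= 1, n_el >= 1,
            D_max > D_min, D_min >= 0)
  structure(list(h = h, gamma = gamma, fov_az = fov_az, fov_el = fov_el,
                 n_az = n_az, n_el = n_el, D_min = D_min, D_max = D_max),
            class = "camera_config")
}

#' Flow noise configuration
#'
#' Additive, independent zero-mean Gaussian noise on each component
#' (azimuth rate, elevation rate) of each valid flow pixel; one draw per
#' pixel component per frame. `sigma_flow` is given on the scale of the flow
#' field itself and corresponds to the per-frame noise level of the sensed
#' flow (the sweep values 0..50 used in the experiments).
#'
#' @param sigma_flow Noise standard deviation (>= 0).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return An object of class `"noise_config"`.
#' @export
noise_config <- function(sigma_flow = 0, seed = NULL) {
  stopifnot(sigma_flow >= 0)
  structure(list(sigma_flow = sigma_flow, seed = seed),
            class = "noise_config")
}

#' Oscillatory-interference model parameters
#'
#' Somatic theta frequency `f` (Hz), velocity gain `beta` (s/cm), spike
#' threshold `theta_spike`, and the three basis directions (degrees) along
#' which dendritic oscillations integrate velocity. The closed-form grid
#' field spacing is `G = 2 / (sqrt(3) * beta * f)` and the per-oscillator
#' band distance `L = 1 / (beta * f)`.
#'
#' @param f Somatic oscillation frequency, Hz.
#' @param beta Velocity modulation gain, s/cm.
#' @param theta_spike Spike threshold on the three-way interference product.
#' @param basis_angles Basis vector directions in degrees; must be mutual
#'   multiples of 60 degrees.
#' @return An object of class `"oscillator_params"`.
#' @export
oscillator_params <- function(f = 7.38, beta = 0.00385, theta_spike = 1.8,
                              basis_angles = c(0, 120, 240)) {
  stopifnot(f > 0, beta > 0, length(basis_angles) == 3)
  d <- outer(basis_angles, basis_angles, "-")
  if (any(abs(d %% 60) > 1e-8 & abs(d %% 60 - 60) > 1e-8))
    stop("basis angles must differ by multiples of 60 degrees")
  structure(list(f = f, beta = beta, theta_spike = theta_spike,
                 basis_angles = basis_angles),
            class = "oscillator_params")
}

#' Ground-truth reset configuration
#'
#' Periodic correction of the path-integrated pose: every `t_reset` minutes
#' the integrated position and orientation are replaced by their
#' ground-truth values and integration continues from the corrected state.
#' `t_reset = Inf` disables the reset.
#'
#' @param t_reset Reset period in minutes (`Inf` = never).
#' @return An object of class `"reset_config"`.
#' @export
reset_config <- function(t_reset = Inf) {
  stopifnot(t_reset > 0)
  structure(list(t_reset = t_reset), class = "reset_config")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap degrees to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
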