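#' Build the spherical sensor grid
#'
#' Pixel centres form a regular lattice in azimuth (theta, measured in the
#' xz-plane from the forward z-axis) and elevation (phi). The camera frame
#' is left-handed: z forward, y up, x right. With the default field of view
#' of +/-120 x +/-60 degrees and 40 x 20 samples the pixel spacing is 6
#' degrees and n = 800.
#'
#' @param cam A [camera_config()].
#' @return An object of class `"sensor_grid"`: vectors `theta`, `phi`
#'   (degrees, pixel centres, azimuth varying fastest), plus `n_az`, `n_el`
#'   and the camera configuration.
#' @export
build_sensor_grid <- function(cam = camera_config()) {
  d_az <- 2 * cam$fov_az / cam$n_az
  d_el <- 2 * cam$fov_el / cam$n_el
  az <- -cam$fov_az + d_az * (seq_len(cam$n_az) - 0.5)
  el <- -cam$fov_el + d_el * (seq_len(cam$n_el) - 0.5)
  g <- expand.grid(theta = az, phi = el)
  structure(list(theta = g$theta, phi = g$phi, n_az = cam$n_az,
                 n_el = cam$n_el, cam = cam),
            class = "sensor_grid")
}

## ground-plane denominator: positive where the ray meets the ground.
## In the camera frame the ray direction is
##   r = (sin(theta) cos(phi), sin(phi), cos(theta) cos(phi))
## and the plane constraint D = h / s with
##   s = sin(gamma) cos(theta) cos(phi) - cos(gamma) sin(phi),
## the inner product of r with the downward ground normal expressed in the
## camera frame; positive tilt (camera down) enlarges the ground-hitting
## region ahead.
plane_denominator <- function(grid, gamma) {
  th <- deg2rad(grid$theta); ph <- deg2rad(grid$phi); g <- deg2rad(gamma)
  sin(g) * cos(th) * cos(ph) - cos(g) * sin(ph)
}

#' Depth of the infinite ground plane
#'
#' Closed-form depth `D = h / s` along each pixel ray for an unbounded
#' ground plane, with `s` the inner product of the ray direction and the
#' (downward) ground normal in the camera frame. Pixels whose rays do not
#' meet the ground (`s <= 0`) are invalid.
#'
#' @param grid A [build_sensor_grid()] result.
#' @param h Eye height, cm.
#' @param gamma Tilt angle, degrees (positive = downward).
#' @return An object of class `"depth_map"`: `D` (cm) and logical `valid`.
#' @export
plane_depth <- function(grid, h, gamma) {
  s <- plane_denominator(grid, gamma)
  valid <- s > 1e-12
  D <- rep(NA_real_, length(s))
  D[valid] <- h / s[valid]
  structure(list(D = D, valid = valid, grid = grid), class = "depth_map")
}

#' Ray-traced depth against the circular platform
#'
#' Intersects every pixel ray (camera at `position` with the given
#' allocentric heading, nodal point at height `h`, optical axis tilted by
#' `gamma`) with the ground disc of radius `platform_radius`. Rays that miss
#' the disc, never reach the ground, or exceed `D_max` are invalid.
#'
#' @param position Length-2 numeric, camera ground position (cm).
#' @param heading Allocentric heading, degrees (0 = +x, counter-clockwise).
#' @param cam A [camera_config()].
#' @param arena An [arena_config()].
#' @param grid Optional precomputed [build_sensor_grid()] for `cam`.
#' @return A `"depth_map"` with the distance along each ray (cm).
#' @export
ray_trace_depth <- function(position, heading, cam = camera_config(),
                            arena = arena_config(), grid = NULL) {
  if (is.null(grid)) grid <- build_sensor_grid(cam)
  if (sum(position^2) > arena$platform_radius^2)
    stop("camera position outside the platform")
  dm <- plane_depth(grid, cam$h, cam$gamma)
  valid <- dm$valid & dm$D > cam$D_min & dm$D <= cam$D_max
  th <- deg2rad(grid$theta); ph <- deg2rad(grid$phi)
  g <- deg2rad(cam$gamma)
  ## horizontal ray components in the heading-aligned frame (x right,
  ## z forward); tilt rotates the camera frame about its x-axis
  rx <- sin(th) * cos(ph)
  rz <- sin(g) * sin(ph) + cos(g) * cos(th) * cos(ph)
  ## ground hit point in arena coordinates
  hd <- deg2rad(heading)
  fx <- cos(hd); fy <- sin(hd)        # forward
  sx <- sin(hd); sy <- -cos(hd)       # right of heading
  gx <- position[1] + dm$D * (rz * fx + rx * sx)
  gy <- position[2] + dm$D * (rz * fy + rx * sy)
  inside <- !is.na(gx) & (gx^2 + gy^2 <= arena$platform_radius^2)
  valid <- valid & inside
  D <- dm$D
  D[!valid] <- NA_real_
  structure(list(D = D, valid = valid, grid = grid), class = "depth_map")
}

rot_tilt <- function(gamma) {
  g <- deg2rad(gamma)
  matrix(c(1, 0, 0,
           0, cos(g), sin(g),
           0, -sin(g), cos(g)), 3, 3)  # column-major: R[2,3] = -sin g
}

#' Visual image motion for arbitrary 3-D self-motion
#'
#' Evaluates the spherical-camera motion field for a 3-D linear velocity `v`
#' (cm/s) and rotational velocity `omega` (deg/s), both given in the
#' ground-aligned frame and rotated into the camera frame by the tilt
#' `gamma`. The translational term scales with inverse depth; the rotational
#' term is depth-free. Output rates are in deg/s.
#'
#' @param grid A [build_sensor_grid()] result.
#' @param depth A `"depth_map"` on the same grid.
#' @param v Length-3 linear velocity (v_x, v_y, v_z), cm/s.
#' @param omega Length-3 rotational velocity (w_x, w_y, w_z), deg/s.
#' @param gamma Tilt angle, degrees.
#' @return An object of class `"flow_field"`: `theta_dot`, `phi_dot`
#'   (deg/s, `NA` on invalid pixels) and the validity mask.
#' @export
image_motion_full <- function(grid, depth, v, omega, gamma = 0) {
  th <- deg2rad(grid$theta); ph <- deg2rad(grid$phi)
  R <- rot_tilt(gamma)
  vc <- as.numeric(R %*% v)
  wc <- as.numeric(R %*% omega)
  ## translational jacobian (angular rate per unit linear velocity / depth)
  t_th <- (-cos(th) / cos(ph)) * vc[1] + (sin(th) / cos(ph)) * vc[3]
  t_ph <- sin(th) * sin(ph) * vc[1] - cos(ph) * vc[2] +
    cos(th) * sin(ph) * vc[3]
  ## rotational jacobian (dimensionless)
  r_th <- (sin(th) * sin(ph) / cos(ph)) * wc[1] - wc[2] +
    (cos(th) * sin(ph) / cos(ph)) * wc[3]
  r_ph <- cos(th) * wc[1] - sin(th) * wc[3]
  theta_dot <- rad2deg(t_th / depth$D) + r_th
  phi_dot <- rad2deg(t_ph / depth$D) + r_ph
  theta_dot[!depth$valid] <- NA_real_
  phi_dot[!depth$valid] <- NA_real_
  structure(list(theta_dot = theta_dot, phi_dot = phi_dot,
                 valid = depth$valid, grid = grid),
            class = "flow_field")
}

#' Visual image motion for curvilinear (planar) self-motion
#'
#' Restriction of [image_motion_full()] to the two degrees of freedom of a
#' ground animal: linear velocity `v_z` along the (ground-parallel) motion
#' direction and rotational velocity `omega_y` about the ground normal.
#'
#' @inheritParams image_motion_full
#' @param v_z Linear speed, cm/s.
#' @param omega_y Rotational velocity, deg/s.
#' @return A `"flow_field"` (deg/s).
#' @export
image_motion_curvilinear <- function(grid, depth, v_z, omega_y, gamma = 0) {
  th <- deg2rad(grid$theta); ph <- deg2rad(grid$phi); g <- deg2rad(gamma)
  t_th <- sin(th) / cos(ph) * cos(g)
  t_ph <- cos(ph) * sin(g) + cos(th) * sin(ph) * cos(g)
  b_th <- -cos(g) + cos(th) * sin(ph) / cos(ph) * sin(g)
  b_ph <- -sin(th) * sin(g)
  theta_dot <- rad2deg(v_z * t_th / depth$D) + b_th * omega_y
  phi_dot <- rad2deg(v_z * t_ph / depth$D) + b_ph * omega_y
  theta_dot[!depth$valid] <- NA_real_
  phi_dot[!depth$valid] <- NA_real_
  structure(list(theta_dot = theta_dot, phi_dot = phi_dot,
                 valid = depth$valid, grid = grid),
            class = "flow_field")
}

#' Ground-plane constrained motion basis
#'
#' Per-pixel basis fields of the constrained flow model
#' `psi_dot = (1/h) a v_z + b omega_y`: `a` folds the ground-plane depth
#' constraint into the translational field (so that dividing by the eye
#' height resolves the speed/depth scaling invariance), `b` is the
#' depth-free rotational field, and `b_perp` is `b` rotated by 90 degrees
#' pixelwise (`b_perp . b = 0`, `|b_perp| = |b|`). With flow in deg/s,
#' `v_z` in cm/s and `omega_y` in deg/s.
#'
#' @param grid A [build_sensor_grid()] result.
#' @param gamma Tilt angle, degrees.
#' @param h Eye height, cm.
#' @return List of three n x 2 matrices `a_field`, `b_field`,
#'   `b_perp_field`, plus the validity mask of the ground-plane constraint.
#' @export
constrained_motion_basis <- function(grid, gamma = 0, h = 3.5) {
  th <- deg2rad(grid$theta); ph <- deg2rad(grid$phi); g <- deg2rad(gamma)
  s <- plane_denominator(grid, gamma)
  t_th <- sin(th) / cos(ph) * cos(g)
  t_ph <- cos(ph) * sin(g) + cos(th) * sin(ph) * cos(g)
  a <- cbind(s * t_th, s * t_ph) * 180 / pi
  b <- cbind(-cos(g) + cos(th) * sin(ph) / cos(ph) * sin(g),
             -sin(th) * sin(g))
  b_perp <- cbind(-b[, 2], b[, 1])
  list(a_field = a, b_field = b, b_perp_field = b_perp,
       valid = s > 1e-12, grid = grid, gamma = gamma, h = h)
}

#' Corrupt a flow field with Gaussian sensing noise
#'
#' Adds an independent zero-mean Gaussian draw to each component of each
#' valid pixel, modelling the error a brightness-based flow estimator would
#' make. One draw per pixel component per frame.
#'
#' @param flow A `"flow_field"`.
#' @param noise A [noise_config()].
#' @return A `"flow_field"` with the same validity mask.
#' @export
add_flow_noise <- function(flow, noise = noise_config()) {
  if (noise$sigma_flow == 0) return(flow)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  nv <- sum(flow$valid)
  flow$theta_dot[flow$valid] <- flow$theta_dot[flow$valid] +
    stats::rnorm(nv, 0, noise$sigma_flow)
  flow$phi_dot[flow$valid] <- flow$phi_dot[flow$valid] +
    stats::rnorm(nv, 0, noise$sigma_flow)
  flow
}

#' Write a flow field as delimited text
#'
#' One row per pixel with the grid angles, both rate components and the
#' validity flag, so fields can be inspected or re-plotted outside R.
#'
#' @param flow A `"flow_field"`.
#' @param file Output path.
#' @export
write_flow_field <- function(flow, file) {
  utils::write.table(
    data.frame(theta = flow$grid$theta, phi = flow$grid$phi,
               theta_dot = flow$theta_dot, phi_dot = flow$phi_dot,
               valid = as.integer(flow$valid)),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Quiver plot of a flow field
#'
#' @param x A `"flow_field"`.
#' @param scale Arrow scale in degrees of plot space per unit flow.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.flow_field <- function(x, scale = 0.05, ...) {
  ok <- x$valid
  graphics::plot(x$grid$theta[ok], x$grid$phi[ok], pch = 16, cex = 0.2,
                 xlab = "azimuth (deg)", ylab = "elevation (deg)", asp = 2,
                 ...)
  graphics::arrows(x$grid$theta[ok], x$grid$phi[ok],
                   x$grid$theta[ok] + scale * x$theta_dot[ok],
                   x$grid$phi[ok] + scale * x$phi_dot[ok],
                   length = 0.02, col = "steelblue")
  invisible(x)
}
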