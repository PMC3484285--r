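#' Template bank for self-motion decoding
#'
#' Precomputes the constrained motion basis on the sensor grid together
#' with the sampled velocity axes the decoder searches over: linear speeds
#' 2..60 cm/s in 0.5 cm/s steps (117 samples) and rotational velocities
#' -4500..4500 deg/s in 20 deg/s steps (451 samples) by default. `sigma_v`
#' and `sigma_omega` are the Gaussian tuning widths of the two objective
#' functions, applied to the matching residuals in the units of the flow
#' field (deg/s; the linear residual additionally carries the eye height in
#' cm).
#'
#' @param cam A [camera_config()] (its `gamma` and `h` are used).
#' @param v_range,v_step Linear velocity axis, cm/s.
#' @param omega_range,omega_step Rotational velocity axis, deg/s.
#' @param sigma_v,sigma_omega Tuning widths.
#' @param grid Optional precomputed sensor grid.
#' @return An object of class `"template_bank"`.
#' @export
template_bank <- function(cam = camera_config(), v_range = c(2, 60),
                          v_step = 0.5, omega_range = c(-4500, 4500),
                          omega_step = 20, sigma_v = 10, sigma_omega = 25,
                          grid = NULL) {
  if (is.null(grid)) grid <- build_sensor_grid(cam)
  basis <- constrained_motion_basis(grid, cam$gamma, cam$h)
  v_samples <- seq(v_range[1], v_range[2], by = v_step)
  omega_samples <- seq(omega_range[1], omega_range[2], by = omega_step)
  stopifnot(length(v_samples) >= 2, length(omega_samples) >= 2)
  structure(list(grid = grid, cam = cam,
                 a_field = basis$a_field, b_field = basis$b_field,
                 b_perp_field = basis$b_perp_field,
                 plane_valid = basis$valid,
                 v_samples = v_samples, omega_samples = omega_samples,
                 sigma_v = sigma_v, sigma_omega = sigma_omega,
                 h = cam$h, gamma = cam$gamma),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf(paste0("<template_bank> %d pixels, %d linear (%.1f..%.1f cm/s)",
                     " + %d rotational (%.0f..%.0f deg/s) templates\n"),
              length(x$grid$theta), length(x$v_samples), min(x$v_samples),
              max(x$v_samples), length(x$omega_samples),
              min(x$omega_samples), max(x$omega_samples)))
  invisible(x)
}

#' Thin a template bank to a total template budget
#'
#' Keeps `n_templates` velocity samples in total, split between the linear
#' and rotational axes in proportion to their default counts (117:451),
#' thinning each axis evenly while preserving its end points.
#'
#' @param bank A [template_bank()].
#' @param n_templates Total number of templates (>= 4).
#' @return A `"template_bank"` with thinned axes.
#' @export
subsample_templates <- function(bank, n_templates) {
  n_v <- length(bank$v_samples); n_w <- length(bank$omega_samples)
  n_tot <- n_v + n_w
  if (n_templates < 4) stop("need at least 4 templates (2 per axis)")
  if (n_templates >= n_tot) return(bank)
  k_v <- max(2L, round(n_templates * n_v / n_tot))
  k_w <- max(2L, n_templates - k_v)
  thin <- function(xs, k) xs[unique(round(seq(1, length(xs),
                                              length.out = k)))]
  bank$v_samples <- thin(bank$v_samples, k_v)
  bank$omega_samples <- thin(bank$omega_samples, k_w)
  bank
}

valid_flow_pixels <- function(flow, bank) {
  ok <- flow$valid & bank$plane_valid &
    is.finite(flow$theta_dot) & is.finite(flow$phi_dot)
  if (!any(ok)) stop("no valid pixels shared by flow field and bank")
  ok
}

#' Match a flow field against linear-velocity templates
#'
#' The rotational flow component is annihilated by projecting each pixel's
#' flow onto `b_perp`; the residual against the speed template `v_j`,
#' scaled by the eye height, is scored with a Gaussian tuning of width
#' `sigma_v` and averaged over the valid pixels:
#' `f(v_j) = mean_l exp(-(psi_l . b_perp_l h - a_l . b_perp_l v_j)^2 /
#' (2 sigma_v^2))`.
#'
#' @param flow A `"flow_field"` on the bank's grid.
#' @param bank A [template_bank()].
#' @return An object of class `"match_profile"`: `axis` (cm/s) and `values`
#'   in (0, 1].
#' @export
match_linear <- function(flow, bank) {
  ok <- valid_flow_pixels(flow, bank)
  psi_bp <- flow$theta_dot[ok] * bank$b_perp_field[ok, 1] +
    flow$phi_dot[ok] * bank$b_perp_field[ok, 2]
  d <- bank$a_field[ok, 1] * bank$b_perp_field[ok, 1] +
    bank$a_field[ok, 2] * bank$b_perp_field[ok, 2]
  cc <- psi_bp * bank$h
  vals <- vapply(bank$v_samples, function(vj) {
    mean(exp(-(cc - d * vj)^2 / (2 * bank$sigma_v^2)))
  }, numeric(1))
  structure(list(axis = bank$v_samples, values = vals, kind = "linear"),
            class = "match_profile")
}

#' Match a flow field against rotational-velocity templates
#'
#' Removes the translational component predicted by the estimated speed
#' `v_hat` and scores the remaining flow against each rotational template
#' `omega_k` with Gaussian tuning of width `sigma_omega`:
#' `f(omega_k) = mean_l exp(-||psi_l - (1/h) a_l v_hat - b_l omega_k||^2 /
#' (2 sigma_omega^2))`.
#'
#' @inheritParams match_linear
#' @param v_hat Estimated linear speed, cm/s.
#' @return A `"match_profile"` with axis in deg/s.
#' @export
match_rotational <- function(flow, bank, v_hat) {
  ok <- valid_flow_pixels(flow, bank)
  r1 <- flow$theta_dot[ok] - bank$a_field[ok, 1] * v_hat / bank$h
  r2 <- flow$phi_dot[ok] - bank$a_field[ok, 2] * v_hat / bank$h
  b1 <- bank$b_field[ok, 1]; b2 <- bank$b_field[ok, 2]
  vals <- vapply(bank$omega_samples, function(wk) {
    mean(exp(-((r1 - b1 * wk)^2 + (r2 - b2 * wk)^2) /
               (2 * bank$sigma_omega^2)))
  }, numeric(1))
  structure(list(axis = bank$omega_samples, values = vals,
                 kind = "rotational"),
            class = "match_profile")
}

#' Read a velocity estimate off a match profile
#'
#' Three readouts: `"max"` returns the axis value at the profile peak
#' (ties resolved to the lowest index); `"vector_sum"` returns the
#' profile-weighted mean of the whole axis; `"local_vector_sum"` (the
#' default used throughout) restricts the weighted mean to a window of 2%
#' of the samples centred on the peak (half-width at least one sample,
#' clipped at the axis ends), interpolating between samples without the
#' boundary bias of the global vector sum.
#'
#' @param profile A `"match_profile"`.
#' @param method One of `"local_vector_sum"`, `"max"`, `"vector_sum"`.
#' @param window_fraction Window size for the local vector sum, as a
#'   fraction of the number of samples.
#' @return The estimated velocity (same units as `profile$axis`).
#' @export
readout_velocity <- function(profile,
                             method = c("local_vector_sum", "max",
                                        "vector_sum"),
                             window_fraction = 0.02) {
  method <- match.arg(method)
  v <- profile$values; a <- profile$axis
  if (!length(v)) stop("empty profile")
  pk <- which.max(v)
  if (method == "max") return(a[pk])
  if (method == "vector_sum") {
    if (sum(v) == 0) return(a[pk])
    return(sum(a * v) / sum(v))
  }
  half <- max(1L, as.integer(round(window_fraction * length(v) / 2)))
  i <- max(1L, pk - half):min(length(v), pk + half)
  if (sum(v[i]) == 0) return(a[pk])
  sum(a[i] * v[i]) / sum(v[i])
}

#' Estimate linear and rotational self-motion from one flow field
#'
#' Composes the two matching stages: the linear profile (rotation
#' annihilated) is read out first; the resulting speed constrains the
#' rotational profile, which is read out second.
#'
#' @inheritParams match_linear
#' @param method Readout method, see [readout_velocity()].
#' @return An object of class `"selfmotion_estimate"`: `v_hat` (cm/s),
#'   `omega_hat` (deg/s), and the peak heights `certainty_v`,
#'   `certainty_omega`.
#' @export
estimate_self_motion <- function(flow, bank,
                                 method = "local_vector_sum") {
  pv <- match_linear(flow, bank)
  v_hat <- readout_velocity(pv, method)
  pw <- match_rotational(flow, bank, v_hat)
  omega_hat <- readout_velocity(pw, method)
  structure(list(v_hat = v_hat, omega_hat = omega_hat,
                 certainty_v = max(pv$values),
                 certainty_omega = max(pw$values)),
            class = "selfmotion_estimate")
}

#' @export
print.selfmotion_estimate <- function(x, ...) {
  cat(sprintf("<selfmotion_estimate> v = %.2f cm/s (peak %.3f), omega = %.1f deg/s (peak %.3f)\n",
              x$v_hat, x$certainty_v, x$omega_hat, x$certainty_omega))
  invisible(x)
}

#' @export
plot.match_profile <- function(x, ...) {
  graphics::plot(x$axis, x$values, type = "l",
                 xlab = if (identical(x$kind, "linear"))
                   "linear velocity (cm/s)" else "rotational velocity (deg/s)",
                 ylab = "match", ...)
  invisible(x)
}

#' Write a match profile as two-column delimited text
#'
#' @param profile A `"match_profile"`.
#' @param file Output path.
#' @export
write_profile <- function(profile, file) {
  utils::write.table(data.frame(velocity = profile$axis,
                                match = profile$values),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
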