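test_that("sensor grid has the documented layout", {
  g <- build_sensor_grid(camera_config())
  expect_length(g$theta, 800)
  expect_equal(sort(unique(diff(sort(unique(g$theta))))), 6)
  expect_true(all(abs(g$theta) <= 120) && all(abs(g$phi) <= 60))

  g1 <- build_sensor_grid(camera_config(n_az = 1, n_el = 1))
  expect_equal(c(g1$theta, g1$phi), c(0, 0))
})

test_that("plane depth matches the closed form and masks the horizon", {
  g <- exact_grid(theta = c(0, 30), phi = c(-30, 0, 20))
  d <- plane_depth(g, h = 3.5, gamma = 0)
  i <- which(g$theta == 0 & g$phi == -30)
  expect_equal(d$D[i], 3.5 / sin(30 * pi / 180), tolerance = 1e-12)
  expect_false(d$valid[which(g$theta == 0 & g$phi == 0)])   # horizon
  expect_false(d$valid[which(g$phi == 20)[1]])              # above horizon

  ## downward tilt brings the central pixels onto the ground
  d30 <- plane_depth(exact_grid(0, 0), h = 3.5, gamma = 30)
  expect_true(d30$valid[1])
  expect_equal(d30$D[1], 3.5 / sin(30 * pi / 180), tolerance = 1e-12)
})

test_that("ray tracing agrees with the plane solution inside the disc", {
  cam <- camera_config()
  arena <- arena_config()
  g <- build_sensor_grid(cam)
  rt <- ray_trace_depth(c(0, 0), heading = 33, cam, arena, g)
  pl <- plane_depth(g, cam$h, cam$gamma)
  ## pixels valid in the ray trace must carry the plane depth
  expect_true(all(rt$valid == (pl$valid & !is.na(rt$D))))
  expect_equal(rt$D[rt$valid], pl$D[rt$valid], tolerance = 1e-12)
  ## at gamma = 0 nothing at or above the horizon is valid
  expect_true(all(g$phi[rt$valid] < 0))
  ## centred camera with downward tilt keeps central pixels valid
  rt30 <- ray_trace_depth(c(0, 0), 0, camera_config(gamma = 30), arena)
  ctr <- abs(rt30$grid$theta) < 22 & abs(rt30$grid$phi) < 22
  expect_true(all(rt30$valid[ctr]))
  expect_error(ray_trace_depth(c(150, 0), 0, cam, arena), "outside")
})

test_that("rays crossing the platform edge are invalidated", {
  cam <- camera_config()
  arena <- arena_config()
  ## camera at the recorded boundary, looking outward: forward ground
  ## pixels fall beyond the platform edge at shallow elevations
  rt <- ray_trace_depth(c(84, 0), heading = 0, cam, arena)
  fwd_far <- rt$grid$phi > -15 & rt$grid$phi < 0 &
    abs(rt$grid$theta) < 10
  expect_true(all(!rt$valid[fwd_far]))
  expect_gt(sum(rt$valid), 0)
})

test_that("image motion superposes and scales with depth", {
  cam <- camera_config()
  g <- build_sensor_grid(cam)
  d <- plane_depth(g, cam$h, 0)
  v <- c(3, -1, 18); w <- c(40, -300, 12)
  f_both <- image_motion_full(g, d, v, w, gamma = 12)
  f_v <- image_motion_full(g, d, v, c(0, 0, 0), gamma = 12)
  f_w <- image_motion_full(g, d, c(0, 0, 0), w, gamma = 12)
  expect_equal(f_both$theta_dot, f_v$theta_dot + f_w$theta_dot,
               tolerance = 1e-12)
  expect_equal(f_both$phi_dot, f_v$phi_dot + f_w$phi_dot,
               tolerance = 1e-12)

  ## doubling speed and depth together leaves the flow unchanged
  d2 <- d; d2$D <- 2 * d$D
  f_scaled <- image_motion_full(g, d2, 2 * v, w, gamma = 12)
  expect_equal(f_scaled$theta_dot, f_both$theta_dot, tolerance = 1e-10)

  ## the rotational term is depth-free
  f_w2 <- image_motion_full(g, d2, c(0, 0, 0), w, gamma = 12)
  expect_equal(f_w2$theta_dot, f_w$theta_dot, tolerance = 1e-12)
})

test_that("canonical single-pixel flows take their closed-form values", {
  g0 <- exact_grid(0, 0)
  d0 <- structure(list(D = 10, valid = TRUE, grid = g0),
                  class = "depth_map")
  ## focus of expansion on the heading: zero flow
  f <- image_motion_full(g0, d0, c(0, 0, 25), c(0, 0, 0), 0)
  expect_equal(c(f$theta_dot, f$phi_dot), c(0, 0), tolerance = 1e-12)
  ## pure yaw at 15 deg/s: azimuth rate -15, elevation rate 0
  f <- image_motion_full(g0, d0, c(0, 0, 0), c(0, 15, 0), 0)
  expect_equal(c(f$theta_dot, f$phi_dot), c(-15, 0), tolerance = 1e-12)
})

test_that("curvilinear model equals the full model restricted", {
  cam <- camera_config()
  g <- build_sensor_grid(cam)
  set.seed(1)
  for (i in 1:20) {
    gamma <- runif(1, -45, 45)
    vz <- runif(1, 2, 60); wy <- runif(1, -4500, 4500)
    d <- plane_depth(g, cam$h, gamma)
    f1 <- image_motion_full(g, d, c(0, 0, vz), c(0, wy, 0), gamma)
    f2 <- image_motion_curvilinear(g, d, vz, wy, gamma)
    expect_equal(f1$theta_dot, f2$theta_dot, tolerance = 1e-9)
    expect_equal(f1$phi_dot, f2$phi_dot, tolerance = 1e-9)
  }
})

test_that("constrained basis reproduces the curvilinear flow on the plane", {
  cam <- camera_config()
  g <- build_sensor_grid(cam)
  for (gamma in c(-30, 0, 25)) {
    bs <- constrained_motion_basis(g, gamma, cam$h)
    d <- plane_depth(g, cam$h, gamma)
    f <- image_motion_curvilinear(g, d, 17, -800, gamma)
    pred_t <- bs$a_field[, 1] * 17 / cam$h + bs$b_field[, 1] * -800
    pred_p <- bs$a_field[, 2] * 17 / cam$h + bs$b_field[, 2] * -800
    ok <- d$valid
    expect_equal(pred_t[ok], f$theta_dot[ok], tolerance = 1e-9)
    expect_equal(pred_p[ok], f$phi_dot[ok], tolerance = 1e-9)
    ## orthogonal complement: b_perp . b = 0, |b_perp| = |b|, pixelwise
    dot <- rowSums(bs$b_field * bs$b_perp_field)
    expect_equal(dot, rep(0, nrow(bs$b_field)), tolerance = 1e-14)
    expect_equal(rowSums(bs$b_field^2), rowSums(bs$b_perp_field^2),
                 tolerance = 1e-14)
  }
  ## forward pixel, no tilt: rotational basis is (-1, 0)
  b0 <- constrained_motion_basis(exact_grid(0, 0), 0, 3.5)
  expect_equal(as.numeric(b0$b_field), c(-1, 0), tolerance = 1e-14)
})

test_that("flow noise is zero-mean, independent, and seed-reproducible", {
  cam <- camera_config()
  g <- build_sensor_grid(cam)
  d <- plane_depth(g, cam$h, 0)
  f <- image_motion_curvilinear(g, d, 20, 100, 0)
  expect_identical(add_flow_noise(f, noise_config(0)), f)

  nz <- lapply(1:150, function(i)
    add_flow_noise(f, noise_config(sigma_flow = 12, seed = i)))
  dth <- unlist(lapply(nz, function(z)
    (z$theta_dot - f$theta_dot)[f$valid]))
  dph <- unlist(lapply(nz, function(z)
    (z$phi_dot - f$phi_dot)[f$valid]))
  expect_equal(sd(dth), 12, tolerance = 0.02)
  expect_equal(mean(dth), 0, tolerance = 0.15)
  expect_lt(abs(cor(dth, dph)), 0.02)
  ## independence across pixels: neighbouring-pixel correlation ~ 0
  m <- sapply(nz, function(z) (z$theta_dot - f$theta_dot)[f$valid][1:2])
  expect_lt(abs(cor(m[1, ], m[2, ])), 0.2)

  a <- add_flow_noise(f, noise_config(5, seed = 99))
  b <- add_flow_noise(f, noise_config(5, seed = 99))
  expect_identical(a, b)
})
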