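make_flow <- function(vz, wy, gamma = 0, cam = camera_config(gamma = gamma)) {
  g <- build_sensor_grid(cam)
  d <- plane_depth(g, cam$h, gamma)
  image_motion_curvilinear(g, d, vz, wy, gamma)
}

test_that("template bank axes have the documented sampling", {
  bk <- template_bank()
  expect_length(bk$v_samples, 117)
  expect_length(bk$omega_samples, 451)
  expect_equal(range(bk$v_samples), c(2, 60))
  expect_equal(range(bk$omega_samples), c(-4500, 4500))
  expect_true(all(diff(bk$v_samples) > 0))
})

test_that("linear matching recovers speed and annihilates rotation", {
  bk <- template_bank()
  p20 <- match_linear(make_flow(20, 0), bk)
  expect_true(all(p20$values > 0 & p20$values <= 1))
  expect_equal(p20$axis[which.max(p20$values)], 20)

  ## profile invariant to the true rotational velocity (annihilation)
  p20r <- match_linear(make_flow(20, 1000), bk)
  expect_equal(p20$values, p20r$values, tolerance = 1e-10)

  ## all-zero flow: residual grows with speed, smallest sample wins
  zf <- make_flow(0, 0)
  pz <- match_linear(zf, bk)
  expect_equal(pz$axis[which.max(pz$values)], 2)
})

test_that("rotational matching recovers the rate given the speed", {
  bk <- template_bank()
  fl <- make_flow(20, 100)
  pw <- match_rotational(fl, bk, v_hat = 20)
  expect_equal(pw$axis[which.max(pw$values)], 100)
  expect_equal(max(pw$values), 1, tolerance = 1e-12)  # exact template

  ## noise lowers the peak but leaves its location
  set.seed(8)
  heights <- replicate(5, {
    nf <- add_flow_noise(fl, noise_config(25))
    pn <- match_rotational(nf, bk, v_hat = 20)
    c(max(pn$values), pn$axis[which.max(pn$values)])
  })
  expect_true(all(heights[1, ] < 1))
  expect_true(all(abs(heights[2, ] - 100) <= 40))
})

test_that("profile readouts behave on constructed profiles", {
  delta <- structure(list(axis = seq(0, 10), values = c(rep(0, 5), 1,
                                                        rep(0, 5))),
                     class = "match_profile")
  expect_equal(readout_velocity(delta, "max"), 5)
  expect_equal(readout_velocity(delta, "vector_sum"), 5)
  expect_equal(readout_velocity(delta, "local_vector_sum"), 5)

  unif <- structure(list(axis = seq(2, 60, 0.5),
                         values = rep(0.3, 117)), class = "match_profile")
  expect_equal(readout_velocity(unif, "vector_sum"), 31)

  ## symmetric peak centred between two samples interpolates
  ax <- seq(0, 100, 10)
  vals <- exp(-(ax - 45)^2 / 200)
  pr <- structure(list(axis = ax, values = vals), class = "match_profile")
  lvs <- readout_velocity(pr, "local_vector_sum")
  i <- which.max(vals); half <- 1
  expect_equal(lvs, sum(ax[(i - 1):(i + 1)] * vals[(i - 1):(i + 1)]) /
                 sum(vals[(i - 1):(i + 1)]))
  expect_gt(lvs, 40); expect_lt(lvs, 50)

  ## tie resolves to the lowest-index peak
  tie <- structure(list(axis = 1:4, values = c(0, 1, 1, 0)),
                   class = "match_profile")
  expect_equal(readout_velocity(tie, "max"), 2)
})

test_that("self-motion estimation is exact on-grid at zero noise", {
  bk <- template_bank()
  for (tv in list(c(20, 0), c(10, 500), c(41.5, -2000))) {
    est <- estimate_self_motion(make_flow(tv[1], tv[2]), bk)
    expect_equal(est$v_hat, tv[1], tolerance = 1e-6)
    expect_equal(est$omega_hat, tv[2], tolerance = 1e-4)
  }
})

test_that("estimation error grows with flow noise", {
  tr <- generate_synthetic_trajectory(20, seed = 21)
  vel <- derive_velocities(tr)
  bk <- template_bank()
  sds <- sapply(c(0, 12.5, 25, 50), function(sg) {
    errs <- sapply(1:3, function(s) {
      set.seed(100 + s)
      es <- estimate_self_motion_series(vel, tr, bk, sigma_flow = sg)
      sd(es$omega_hat - vel$omega_y)
    })
    mean(errs)
  })
  expect_true(all(diff(sds) > 0))
})

test_that("template subsampling spans the ranges and degrades gracefully", {
  bk <- template_bank()
  expect_identical(subsample_templates(bk, 568), bk)
  bk10 <- subsample_templates(bk, 10)
  expect_equal(range(bk10$v_samples), c(2, 60))
  expect_equal(range(bk10$omega_samples), c(-4500, 4500))
  expect_error(subsample_templates(bk, 3), "at least")

  tr <- generate_synthetic_trajectory(10, seed = 31)
  vel <- derive_velocities(tr)
  err_n <- sapply(c(10, 150, 568), function(n) {
    bn <- subsample_templates(bk, n)
    set.seed(7)
    es <- estimate_self_motion_series(vel, tr, bn, sigma_flow = 25)
    sd(es$omega_hat - vel$omega_y)
  })
  expect_gt(err_n[1], 2 * err_n[2])          # few templates hurt badly
  expect_gt(err_n[2], err_n[3])              # still improving toward full
})

test_that("two-stage decoding matches a brute-force joint search", {
  cam <- camera_config()
  bk <- template_bank(cam, v_step = 2, omega_step = 100)
  set.seed(3)
  for (i in 1:5) {
    vz <- runif(1, 5, 55); wy <- runif(1, -4000, 4000)
    fl <- make_flow(vz, wy)
    fl <- add_flow_noise(fl, noise_config(10))
    est <- estimate_self_motion(fl, bk)
    ## joint Euclidean objective over the full template product grid
    ok <- fl$valid & bk$plane_valid
    t1 <- fl$theta_dot[ok]; t2 <- fl$phi_dot[ok]
    a1 <- bk$a_field[ok, 1]; a2 <- bk$a_field[ok, 2]
    b1 <- bk$b_field[ok, 1]; b2 <- bk$b_field[ok, 2]
    obj <- outer(seq_along(bk$v_samples), seq_along(bk$omega_samples),
                 Vectorize(function(j, k) {
                   vj <- bk$v_samples[j]; wk <- bk$omega_samples[k]
                   sum((t1 - a1 * vj / cam$h - b1 * wk)^2 +
                         (t2 - a2 * vj / cam$h - b2 * wk)^2)
                 }))
    jk <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    expect_lte(abs(est$v_hat - bk$v_samples[jk[1]]), 2)
    expect_lte(abs(est$omega_hat - bk$omega_samples[jk[2]]), 100)
  }
})
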