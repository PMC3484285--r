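test_that("cleaning rules fire on the canonical offending patterns", {
  cfg <- preprocess_config()

  ## sharp turn: a 91-degree heading change gets an interpolated midpoint
  ## in the outgoing segment on the first pass
  p <- position_series(t = c(0, 0.02, 0.04, 0.06),
                       x = c(0, 1, 1 + cos(91 * pi / 180),
                             1 + 2 * cos(91 * pi / 180)),
                       y = c(0, 0, sin(91 * pi / 180),
                             2 * sin(91 * pi / 180)))
  out <- suppressWarnings(preprocess_trajectory(p, cfg, max_iter = 1))
  expect_gt(nrow(out), nrow(p))
  mid <- c((p$x[2] + p$x[3]) / 2, (p$y[2] + p$y[3]) / 2)
  hit <- any(abs(out$x - mid[1]) < 1e-12 & abs(out$y - mid[2]) < 1e-12)
  expect_true(hit)

  ## sub-threshold displacement (0.04 cm = 2 cm/s) is removed
  p <- position_series(t = (0:3) * 0.02, x = c(0, 0.5, 0.54, 1.0),
                       y = rep(0, 4))
  out <- preprocess_trajectory(p, cfg)
  expect_equal(nrow(out), 3)
  expect_false(any(abs(out$x - 0.54) < 1e-12))

  ## over-long step (1.4 cm = 70 cm/s) gets a midpoint
  p <- position_series(t = (0:3) * 0.02, x = c(0, 0.5, 1.9, 2.4),
                       y = rep(0, 4))
  out <- preprocess_trajectory(p, cfg)
  expect_true(any(abs(out$x - 1.2) < 1e-12))
  expect_true(all(step_lengths <- sqrt(diff(out$x)^2 + diff(out$y)^2) <=
                    cfg$max_step + 1e-12))
})

test_that("an already-clean run is a fixpoint and cleaning is idempotent", {
  p <- straight_run(50)
  out <- preprocess_trajectory(p)
  expect_equal(out$x, p$x)
  expect_equal(out$y, p$y)
  expect_equal(attr(out, "changed_fraction"), 0)

  q <- jittered_walk(seed = 2)
  c1 <- preprocess_trajectory(q)
  c2 <- preprocess_trajectory(c1)
  expect_equal(c1$x, c2$x)
  expect_equal(c1$y, c2$y)
})

test_that("after cleaning no consecutive pair violates any threshold", {
  cfg <- preprocess_config()
  for (seed in 1:3) {
    out <- preprocess_trajectory(jittered_walk(seed), cfg)
    d <- sqrt(diff(out$x)^2 + diff(out$y)^2)
    expect_true(all(d >= cfg$min_step - 1e-12))
    expect_true(all(d <= cfg$max_step + 1e-12))
    h <- atan2(diff(out$y), diff(out$x)) * 180 / pi
    turn <- abs((diff(h) + 180) %% 360 - 180)
    expect_true(all(turn <= cfg$max_turn_per_step + 1e-9))
  }
})

test_that("degenerate cleaning inputs raise errors", {
  expect_error(preprocess_trajectory(straight_run(2)), "3 samples")
  expect_error(position_series(t = c(0, 0.02, 0.02), x = 1:3, y = 1:3),
               "increasing")
})

test_that("velocities derive from tangent-heading finite differences", {
  ## straight +x at 10 cm/s
  v <- derive_velocities(straight_run(20, speed = 10))
  expect_equal(v$v_z, rep(10, 20), tolerance = 1e-10)
  expect_equal(v$omega_y, rep(0, 20), tolerance = 1e-10)
  expect_equal(v$phi_hd, rep(0, 20), tolerance = 1e-10)

  ## quarter circle in 1 s: mean rotational velocity 90 deg/s
  n <- 51
  ang <- seq(0, pi / 2, length.out = n)
  p <- position_series(t = seq(0, 1, length.out = n),
                       x = 20 * cos(ang), y = 20 * sin(ang))
  v <- derive_velocities(p)
  expect_equal(mean(v$omega_y), 90, tolerance = 1)
})

test_that("cleaned trajectories yield in-range velocities", {
  out <- preprocess_trajectory(jittered_walk(seed = 4))
  v <- derive_velocities(out)
  expect_true(all(v$v_z >= 2.5 - 1e-9))
  expect_true(all(v$v_z <= 60 + 1e-9))
  expect_true(all(abs(v$omega_y) <= 4500 + 1e-6))
})

test_that("synthetic trajectories match the prescribed statistics", {
  tr <- generate_synthetic_trajectory(60, seed = 9)
  expect_equal(nrow(tr), 3000)
  expect_true(all(tr$x^2 + tr$y^2 <= 85^2 + 1e-9))

  tr2 <- generate_synthetic_trajectory(60, seed = 9)
  expect_identical(tr$x, tr2$x)

  long <- generate_synthetic_trajectory(1080, seed = 1)
  v <- derive_velocities(long)
  expect_true(max(v$v_z) <= 60 + 1e-9)
  h <- hist(v$v_z, breaks = seq(0, 62, 1), plot = FALSE)
  mode_speed <- h$mids[which.max(h$counts)]
  expect_gte(mode_speed, 7.5)
  expect_lte(mode_speed, 12.5)

  ## spatial occupancy covers >= 90% of 10-cm bins over 18 minutes
  br <- seq(-90, 90, 10)
  occ <- table(cut(long$x, br), cut(long$y, br)) > 0
  mids <- br[-1] - 5
  inside <- outer(mids, mids, function(a, b) sqrt(a^2 + b^2) <= 80)
  expect_gte(sum(occ & inside) / sum(inside), 0.9)
})

test_that("trajectory files round-trip and NaN blocks are handled", {
  f <- tempfile(fileext = ".tsv")
  tr <- generate_synthetic_trajectory(5, seed = 3)
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(back$x, tr$x, tolerance = 1e-8)
  expect_equal(back$t, tr$t, tolerance = 1e-8)

  ## interior NaN block: the longest complete run is returned
  writeLines(c("t x y", "0.00 1 1", "0.02 2 2", "0.04 NaN 3",
               "0.06 4 4", "0.08 5 5", "0.10 6 6"), f)
  got <- read_trajectory(f)
  expect_equal(got$x, c(4, 5, 6))

  writeLines(character(0), f)
  expect_error(read_trajectory(f), "empty")

  writeLines(c("0 1 2", "0.02 3"), f)
  expect_error(read_trajectory(f), "line")
})
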