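rigid_series <- function(roll_deg = 0, pitch_deg = 0, nframes = 3,
                         bl = 3, shift = c(0, 0, 0)) {
  base <- hoverstab:::landmark_template(bl)
  ctr <- c(0.45 * bl, 0, 0)
  phi <- roll_deg * pi / 180; psi <- pitch_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(phi), -sin(phi)),
              c(0, sin(phi), cos(phi)))
  ry <- rbind(c(cos(psi), 0, sin(psi)), c(0, 1, 0),
              c(-sin(psi), 0, cos(psi)))
  rot <- t(ry %*% rx %*% (t(base) - ctr) + ctr)
  pts <- array(NA_real_, c(nframes, nrow(base), 3),
               dimnames = list(NULL, rownames(base), c("x", "y", "z")))
  for (i in seq_len(nframes)) pts[i, , ] <- sweep(rot, 2, shift, `+`)
  landmark_series(pts, fps = 100, bl = bl)
}

test_that("roll and pitch are read from the eye segment and body axis", {
  s <- rigid_series(roll_deg = 10)
  rp <- roll_pitch(s, reference = "absolute")
  expect_equal(rp$roll_max_excursion, 10, tolerance = 1e-8)
  expect_equal(rp$pitch_max_excursion, 0, tolerance = 1e-8)
  s2 <- rigid_series(pitch_deg = 7)
  rp2 <- roll_pitch(s2, reference = "absolute")
  expect_equal(rp2$pitch_max_excursion, 7, tolerance = 1e-8)
  expect_equal(rp2$roll_max_excursion, 0, tolerance = 1e-6)
  # a static series has zero excursion about its own mean posture
  rp3 <- roll_pitch(rigid_series(roll_deg = 3, pitch_deg = 2))
  expect_equal(rp3$roll_max_excursion, 0, tolerance = 1e-10)
  expect_equal(rp3$pitch_max_excursion, 0, tolerance = 1e-10)
})

test_that("posture metrics are invariant to translation and yaw", {
  plan <- synth_plan(seed = 6)
  s <- gen_landmark_series(plan)
  rp <- roll_pitch(s)
  # translate
  s_t <- s
  s_t$points <- sweep(s$points, 3, c(12, -4, 7), `+`)
  rp_t <- roll_pitch(s_t)
  expect_equal(rp_t$roll, rp$roll, tolerance = 1e-8)
  expect_equal(rp_t$pitch, rp$pitch, tolerance = 1e-8)
  # yaw-rotate the whole series about the vertical axis
  g <- 35 * pi / 180
  rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  s_y <- s
  for (i in seq_len(dim(s$points)[1]))
    s_y$points[i, , ] <- s$points[i, , ] %*% t(rz)
  rp_y <- roll_pitch(s_y)
  expect_equal(rp_y$roll_max_excursion, rp$roll_max_excursion,
               tolerance = 1e-4)
  expect_equal(rp_y$pitch_max_excursion, rp$pitch_max_excursion,
               tolerance = 1e-4)
})

test_that("body angle is the signed elevation of the eye over the peduncle", {
  expect_equal(body_angle(eye = c(0, 0, 1), peduncle = c(10, 0, 1)), 0)
  expect_equal(body_angle(eye = c(0, 0, 2), peduncle = c(10, 0, 1)),
               asin(1 / sqrt(101)) * 180 / pi)
  expect_equal(body_angle(eye = c(0, 0, 2), peduncle = c(10, 0, 1)),
               5.71, tolerance = 1e-2)
  # head-down mirrors to the negated angle
  expect_equal(body_angle(eye = c(0, 0, 0), peduncle = c(10, 0, 1)),
               -body_angle(eye = c(0, 0, 2), peduncle = c(10, 0, 1)))
  expect_error(body_angle(eye = c(1, 1, 1), peduncle = c(1, 1, 1)),
               "coincide")
})

test_that("Menger curvature is 1/R on circles and 0 on lines", {
  expect_equal(curvature_menger(c(10, 0), c(0, 10), c(-10, 0)), 0.1)
  # random circle points: kappa = 1/R whatever the arc
  set.seed(4)
  for (k in 1:5) {
    r <- runif(1, 0.5, 20)
    th <- sort(runif(3, 0, 2 * pi))
    p <- lapply(th, function(a) r * c(cos(a), sin(a)))
    expect_equal(curvature_menger(p[[1]], p[[2]], p[[3]]), 1 / r,
                 tolerance = 1e-10)
  }
  expect_equal(curvature_menger(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3)), 0)
  # doubling all coordinates halves the curvature
  expect_equal(curvature_menger(c(20, 0), c(0, 20), c(-20, 0)), 0.05)
  expect_error(curvature_menger(c(1, 2), c(1, 2), c(3, 4)), "duplicated")
})

test_that("phase lag hits the definitional endpoints and analytic shifts", {
  t <- seq(0, 3, by = 1e-3)
  l <- sin(4 * pi * t)
  expect_equal(phase_lag(l, l, 1000)$phase_deg, 0)
  expect_equal(phase_lag(l, -l, 1000)$phase_deg, 180, tolerance = 0.1)
  pl <- phase_lag(l, sin(4 * pi * t - pi / 2), 1000)
  expect_equal(pl$phase_deg, 90, tolerance = 0.5)
  expect_equal(abs(pl$lag_s), 0.125, tolerance = 1e-3)
  expect_equal(pl$period_s, 0.5, tolerance = 1e-3)
  # symmetric in its arguments after folding
  r <- sin(4 * pi * t - 1.1)
  expect_equal(phase_lag(l, r, 1000)$phase_deg,
               phase_lag(r, l, 1000)$phase_deg, tolerance = 1e-6)
  expect_error(phase_lag(rep(1, 100), rep(1, 100), 100),
               "non-oscillatory")
})

test_that("fin distance integrates the path in body lengths per second", {
  still <- matrix(1, nrow = 50, ncol = 3)
  expect_equal(fin_distance(still, 100, 3), 0)
  # circle of radius 0.5 at 3 Hz, bl 3: 2*pi*r*f/bl = pi
  t1 <- seq(0, 1, by = 1 / 1000)
  circ <- cbind(0, 0.5 * cos(6 * pi * t1), 0.5 * sin(6 * pi * t1))
  expect_equal(fin_distance(circ, 1000, 3), pi, tolerance = 0.005 * pi)
  # refining the sampling changes the result by < 1%
  t2 <- seq(0, 1, by = 1 / 2000)
  circ2 <- cbind(0, 0.5 * cos(6 * pi * t2), 0.5 * sin(6 * pi * t2))
  expect_lt(abs(fin_distance(circ2, 2000, 3) - fin_distance(circ, 1000, 3)) /
              fin_distance(circ, 1000, 3), 0.01)
})

test_that("cycle extraction counts complete fin beats", {
  tt <- seq(0, 3, by = 1e-2)
  expect_length(extract_cycles(sin(2 * pi * tt)), 3)
  tt2 <- seq(0, 3.5, by = 1e-2)
  expect_length(extract_cycles(sin(2 * pi * tt2)), 3)
  expect_error(extract_cycles(sin(2 * pi * seq(0, 0.4, by = 1e-2))),
               regexp = "cycle|peak|dips")
  # noisy beats: count matches the noiseless ground truth across seeds
  tt3 <- seq(0, 4.4, by = 1e-2)
  clean <- sin(2 * pi * tt3 - pi / 3)
  truth <- length(extract_cycles(clean))
  counts <- vapply(1:100, function(k) {
    set.seed(k)
    length(extract_cycles(clean + rnorm(length(clean), 0, 0.05)))
  }, numeric(1))
  expect_true(all(counts == truth))
})

test_that("the kinematics summary reports the generated motion", {
  plan <- synth_plan(seed = 8)
  s <- gen_landmark_series(plan)
  ks <- kinematics_summary(s)
  expect_equal(ks$roll_max_excursion, 4, tolerance = 0.05)
  expect_equal(ks$pitch_max_excursion, 2, tolerance = 0.05)
  expect_equal(ks$phase_lag_deg, 180, tolerance = 0.5)
  expect_equal(ks$curvature, 0, tolerance = 1e-8)  # straight body
  expect_gt(ks$fin_dist_pect_l, 0)
})
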