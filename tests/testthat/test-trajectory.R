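test_that("arc_length sums segment lengths", {
  expect_equal(arc_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(arc_length(rbind(c(0, 0), c(1, 0), c(1, 1))), 2)
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  expect_equal(arc_length(sq), 40)
  expect_error(arc_length(rbind(c(0, 0))), class = "degenerate_trajectory")
})

test_that("trajectory CSV reader groups, sorts and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,fish_id,t_s,x_cm,y_cm",
               "b,f2,1,11,11",
               "a,f1,0,10,10",
               "b,f2,0,10,10",
               "a,f1,1,11,12",
               "a,f1,2,12,13"), path)
  trs <- read_trajectories(path)
  expect_length(trs, 2)
  expect_equal(length(trs$a$t), 3)
  expect_equal(trs$b$t, c(0, 1))       # time-sorted despite interleaving
  expect_equal(trs$a$y, c(10, 12, 13))

  writeLines(c("trial_id,fish_id,t_s,x_cm,y_cm",
               "a,f1,0,10,10", "a,f1,1,11,11", "a,f1,1,12,12"), path)
  expect_error(read_trajectories(path), class = "validation_error")
  writeLines(c("trial_id,fish_id,t_s,x_cm", "a,f1,0,10"), path)
  expect_error(read_trajectories(path), class = "validation_error")
  writeLines(c("trial_id,fish_id,t_s,x_cm,y_cm", "a,f1,0,10,500"), path)
  expect_error(read_trajectories(path, tank_side = 130),
               class = "validation_error")
})

test_that("modified-Akima interpolation matches the reference scheme", {
  # expected values frozen from an independent makima implementation
  # (knots parameterised by cumulative chord length, 7 equal stations)
  pts <- rbind(c(0, 0), c(1, 0), c(2, 1), c(3, 3), c(4, 4))
  ip <- interpolate_1000(pts, n = 7)
  expect_equal(ip$points[, 1],
               c(0, 1.00875315, 1.76156993, 2.29798163, 2.70534592,
                 3.24675504, 4),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(ip$points[, 2],
               c(0, 0.00398268336, 0.67557547890, 1.53634029481,
                 2.47931359296, 3.31208131086, 4),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("interpolation endpoints, station count and linear exactness hold", {
  seg <- rbind(c(0, 0), c(999, 0))
  ip <- interpolate_1000(seg)
  expect_equal(nrow(ip$points), 1000)
  expect_equal(ip$points[1, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(ip$points[1000, ], c(999, 0), ignore_attr = TRUE)
  # linear case is exact: stations at multiples of 1 cm, collinear
  expect_equal(ip$points[, 1], seq(0, 999, length.out = 1000),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(max(abs(ip$points[, 2])), 0, tolerance = 1e-12)
  # 2-point input reduces to linear interpolation for any heading
  seg2 <- rbind(c(0, 0), c(3, 4))
  ip2 <- interpolate_1000(seg2, n = 11)
  expect_equal(ip2$points[, 1], seq(0, 3, length.out = 11),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(interpolate_1000(rbind(c(1, 1), c(1, 1))),
               class = "degenerate_trajectory")
})

test_that("interpolated L-path length agrees with dense resampling", {
  # 1 Hz-like knots every 3 cm along a right-angle path
  xs <- c(seq(0, 30, by = 3), rep(30, 10))
  ys <- c(rep(0, 11), seq(3, 30, by = 3))
  path <- cbind(xs, ys)
  ip <- interpolate_1000(path)
  dense <- interpolate_1000(path, n = 20000)
  expect_equal(arc_length(ip$points), arc_length(dense$points),
               tolerance = 1e-3)
  # idempotence: exact on straight equal-spacing paths; on smooth curves
  # the chordal re-parameterisation shifts stations by a physically
  # negligible amount (sub-thousandth of a cm)
  st <- interpolate_1000(rbind(c(2, 1), c(42, 31)))
  st2 <- interpolate_1000(st$points)
  expect_lt(max(abs(st2$points - st$points)), 1e-9)
  xs2 <- seq(0, 40, by = 2)
  smooth <- cbind(xs2, 3 * sin(xs2 / 12))
  ips <- interpolate_1000(smooth)
  ips2 <- interpolate_1000(ips$points)
  expect_lt(max(abs(ips2$points - ips$points)), 1e-3)
})

test_that("pointwise distances pair by index", {
  a <- interpolate_1000(rbind(c(0, 0), c(10, 0)))
  expect_equal(pointwise_distances(a, a)$mean, 0)
  b <- interpolate_1000(rbind(c(3, 4), c(13, 4)))
  pd <- pointwise_distances(a, b)
  expect_equal(pd$distances, rep(5, 1000), tolerance = 1e-12)
  expect_equal(pd$mean, 5, tolerance = 1e-12)
  # orthogonal unit segments from the same origin: d_k = sqrt(2) * s_k,
  # mean = sqrt(2)/2 (discrete mean of s_k over equal stations is 1/2)
  u1 <- interpolate_1000(rbind(c(0, 0), c(1, 0)))
  u2 <- interpolate_1000(rbind(c(0, 0), c(0, 1)))
  expect_equal(pointwise_distances(u1, u2)$mean, sqrt(2) / 2,
               tolerance = 1e-9)
  short <- interpolate_1000(rbind(c(0, 0), c(1, 0)), n = 10)
  expect_error(pointwise_distances(a, short), class = "contract_error")
})

test_that("pointwise mean distance is translation-equivariant and rotation-invariant", {
  set.seed(20001)
  pts_a <- cbind(cumsum(runif(8, 0.5, 2)), cumsum(rnorm(8)))
  pts_b <- cbind(cumsum(runif(8, 0.5, 2)), cumsum(rnorm(8)))
  base <- pointwise_distances(interpolate_1000(pts_a),
                              interpolate_1000(pts_b))$mean
  shift <- c(7, -3)
  shifted <- pointwise_distances(
    interpolate_1000(sweep(pts_a, 2, shift, "+")),
    interpolate_1000(sweep(pts_b, 2, shift, "+")))$mean
  expect_equal(shifted, base, tolerance = 1e-9)
  phi <- 0.7
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  rotated <- pointwise_distances(interpolate_1000(pts_a %*% R),
                                 interpolate_1000(pts_b %*% R))$mean
  # componentwise makima is only approximately rotation-equivariant (the
  # slope weights are nonlinear in the coordinates); sub-percent agreement
  expect_equal(rotated, base, tolerance = 5e-3)
  # the straight-segment case is exact under rotation
  s1 <- rbind(c(0, 0), c(10, 0)); s2 <- rbind(c(0, 2), c(10, 5))
  b0 <- pointwise_distances(interpolate_1000(s1), interpolate_1000(s2))$mean
  b1 <- pointwise_distances(interpolate_1000(s1 %*% R),
                            interpolate_1000(s2 %*% R))$mean
  expect_equal(b1, b0, tolerance = 1e-9)
})

test_that("common-length cropping truncates the longer path only", {
  long <- rbind(c(0, 0), c(100, 0))
  pim <- build_model_trajectory(default_config, "PI", "lateral")
  cc <- crop_to_common_length(long, pim$polyline)
  expect_equal(arc_length(cc$a), 38.6, tolerance = 1e-9)
  expect_equal(arc_length(cc$b), 38.6, tolerance = 1e-9)
  short <- rbind(c(0, 0), c(20, 0))
  cc2 <- crop_to_common_length(short, pim$polyline)
  expect_equal(arc_length(cc2$a), 20, tolerance = 1e-9)
  expect_equal(arc_length(cc2$b), 20, tolerance = 1e-9)
  expect_equal(cc2$a, short, ignore_attr = TRUE)  # shorter side unchanged
  # symmetric in which input is longer; never lengthens
  cc3 <- crop_to_common_length(pim$polyline, long)
  expect_equal(arc_length(cc3$a), arc_length(cc3$b), tolerance = 1e-9)
  same <- crop_to_common_length(short, short)
  expect_equal(same$a, short, ignore_attr = TRUE)
})

test_that("turn-back cropping finds the scripted return run", {
  # 10 s straight away from the chamber, then straight back toward it
  away <- straight_traj(45, n = 11, step = 2, start = c(0, 0))
  back_x <- away$x[11] - (1:8) * 2 * cos(pi / 4)
  back_y <- away$y[11] - (1:8) * 2 * sin(pi / 4)
  tr <- trajectory("t", "f", 0:18, c(away$x, back_x), c(away$y, back_y))
  cr <- crop_at_turnback(tr, chamber = c(0, 0))
  expect_equal(cr$crop_index, 11L)
  expect_equal(length(cr$trajectory$t), 11L)
  # a path that never orients back is only window-truncated
  tr2 <- straight_traj(45, n = 80, step = 1)
  cr2 <- crop_at_turnback(tr2, chamber = c(0, 0), analysis_window = 60)
  expect_true(is.na(cr2$crop_index))
  expect_equal(length(cr2$trajectory$t), 61L)   # samples at t = 0..60
  # synthetic swimmer: detected crop within one sample of scripted truth
  sp <- synthetic_spec(heading_noise_kappa = Inf, speed_sd = 0,
                       speed_mean = 38.6 / 10)
  sim <- simulate_trajectory("PI", "lateral", default_config, sp, seed = 20002)
  door <- displaced_chamber_position(default_config, "lateral")
  cr3 <- crop_at_turnback(sim$trajectory, door)
  expect_lte(abs(cr3$crop_index - sim$truth$turn_index), 1L)
})
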