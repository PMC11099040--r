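test_that("sd_uniform follows the (b - a)/sqrt(12) definition", {
  expect_equal(sd_uniform(0, 12), 12 / sqrt(12), tolerance = 1e-12)
  expect_equal(round(sd_uniform(0, 12), 4), 3.4641)
  expect_equal(sd_uniform(5, 5), 0)
  expect_equal(round(sd_uniform(2, 4), 4), 0.5774)
  expect_error(sd_uniform(4, 2), class = "contract_error")
})

test_that("random trajectories are straight, seeded and uniform in heading", {
  set.seed(20003)
  r1 <- generate_random_trajectory(38.6, start = c(5, 5))
  set.seed(20003)
  r2 <- generate_random_trajectory(38.6, start = c(5, 5))
  expect_identical(r1, r2)
  expect_equal(arc_length(r1), 38.6, tolerance = 1e-12)
  expect_equal(arc_length(generate_random_trajectory(10)), 10,
               tolerance = 1e-12)
  expect_error(generate_random_trajectory(0), class = "contract_error")
  # heading distribution uniform on [0, 180): KS distance < 0.02 at n = 1e4
  set.seed(20004)
  heads <- replicate(10000, {
    p <- generate_random_trajectory(1)
    (atan2(p[2, 2] - p[1, 2], p[2, 1] - p[1, 1]) * 180 / pi) %% 360
  })
  expect_true(all(heads >= 0 & heads < 180))
  ks <- max(abs(sort(heads) / 180 - (seq_along(heads) - 0.5) / length(heads)))
  expect_lt(ks, 0.02)
})

test_that("null distribution satisfies its definitional invariants", {
  obs <- straight_traj(45, n = 14, step = 3)
  pim <- build_model_trajectory(default_config, "PI", "lateral")
  nul <- build_null(obs, pim, n = 2000, seed = 20005)
  expect_lte(nul$a, nul$mu); expect_lte(nul$mu, nul$b)
  expect_equal(nul$sd_uniform, (nul$b - nul$a) / sqrt(12), tolerance = 1e-12)
  expect_equal(nul$sd_normal, sd(nul$mean_distances), tolerance = 1e-12)
  expect_gte(nul$q20, nul$a); expect_lte(nul$q20, nul$b)
  expect_equal(mean(nul$mean_distances <= nul$q20), 0.2, tolerance = 0.01)
  # seeded determinism
  nul2 <- build_null(obs, pim, n = 2000, seed = 20005)
  expect_identical(nul$mean_distances, nul2$mean_distances)
  # a straight observed path is itself in the null family, so some random
  # heading comes close and the minimum is near zero at n = 10,000
  nul3 <- build_null(obs, pim, n = 10000, seed = 20006)
  expect_lt(nul3$a, 0.1)
  expect_warning(build_null(obs, pim, n = 50, seed = 1), "fewer than 100")
  expect_error(build_null(obs, pim, n = 0), class = "contract_error")
})

test_that("null build equals the generic crop/interpolate/distance route", {
  # oracle: one random trajectory scored through the public operations
  obs <- headings_traj(c(40, 50, 45, 60, 44, 30, 45, 52, 48, 45, 41, 55),
                       step = 3.2)
  pim <- build_model_trajectory(default_config, "PI", "lateral")
  nul <- build_null(obs, pim, n = 200, seed = 20007)
  L <- min(arc_length(cbind(obs$x, obs$y)), pim$total_length)
  th <- withr::with_seed(20007, runif(200, 0, 180))
  for (i in c(1, 57, 200)) {
    rnd <- rbind(c(obs$x[1], obs$y[1]),
                 c(obs$x[1], obs$y[1]) +
                   L * c(cos(th[i] * pi / 180), sin(th[i] * pi / 180)))
    cc <- crop_to_common_length(cbind(obs$x, obs$y), rnd)
    pd <- pointwise_distances(interpolate_1000(cc$a), interpolate_1000(cc$b))
    expect_equal(nul$mean_distances[i], pd$mean, tolerance = 1e-9)
  }
})

test_that("closest model ranks by mean pointwise distance", {
  models <- lateral_models()
  # observed identical to the APC polyline
  apc <- models$APC$polyline
  obs <- trajectory("t", "f", 0:1, apc[, 1], apc[, 2])
  cm <- closest_model(obs, models, boot = FALSE)
  expect_equal(cm$ranking$strategy[1], "APC")
  expect_equal(cm$ranking$mean_distance[1], 0, tolerance = 1e-9)
  # observed parallel to PI at perpendicular offset 2 -> PI first, mean 2
  pi_poly <- models$PI$polyline
  perp <- c(-sin(pi / 4), cos(pi / 4)) * 2
  obs2 <- trajectory("t2", "f", 0:1, pi_poly[, 1] + perp[1],
                     pi_poly[, 2] + perp[2])
  cm2 <- closest_model(obs2, models, boot = FALSE)
  expect_equal(cm2$ranking$strategy[1], "PI")
  expect_equal(cm2$ranking$mean_distance[1], 2, tolerance = 1e-9)
  # noiseless synthetic RR swimmer is closest to RR
  sp <- synthetic_spec(heading_noise_kappa = Inf, speed_sd = 0,
                       speed_mean = 54.5 / 12)
  sim <- simulate_trajectory("RR", "lateral", default_config, sp,
                             seed = 20008)
  door <- displaced_chamber_position(default_config, "lateral")
  cr <- crop_at_turnback(sim$trajectory, door)
  cm3 <- closest_model(cr$trajectory, models, boot = TRUE, seed = 1)
  expect_equal(cm3$ranking$strategy[1], "RR")
  # block-bootstrap contrasts cover all three pairs with finite intervals
  expect_equal(nrow(cm3$contrasts), 3)
  expect_true(all(cm3$contrasts$ci_lo <= cm3$contrasts$ci_hi))
  expect_error(closest_model(obs, models[c("PI", "APC")]),
               class = "config_error")
})

test_that("classification thresholds follow the selected rule", {
  models <- lateral_models()
  pi_poly <- models$PI$polyline
  obs <- trajectory("t", "f", 0:1, pi_poly[, 1], pi_poly[, 2])  # best = PI, 0
  nul <- fake_null(mu = 30, sd_uniform = 8, sd_normal = 5, q20 = 22)
  expect_equal(classify_trial(obs, models, nul, "sd_uniform")$label, "PI")
  expect_equal(classify_trial(obs, models, nul, "sd_uniform")$threshold, 22)
  expect_equal(classify_trial(obs, models, nul, "sd_normal")$threshold, 25)
  expect_equal(classify_trial(obs, models, nul, "q20")$threshold, 22)
  # boundary arithmetic: a path away from every model is RANDOM when its
  # best distance sits above the threshold, a model label when below
  obs2 <- straight_traj(315, n = 5, step = 8,
                        start = pi_poly[1, ])   # heads away from all models
  best_d <- closest_model(obs2, models, boot = FALSE)$ranking$mean_distance[1]
  above <- fake_null(mu = best_d + 1, sd_uniform = 2)   # threshold best_d - 1
  cl2 <- classify_trial(obs2, models, above, "sd_uniform")
  expect_equal(cl2$best_distance, best_d, tolerance = 1e-9)
  expect_equal(cl2$label, "RANDOM")
  # degenerate null (sd 0): threshold reduces to mu, just above best
  below <- fake_null(mu = best_d + 1, sd_uniform = 0)
  expect_equal(classify_trial(obs2, models, below, "sd_uniform")$label,
               cl2$best_strategy)
  expect_error(classify_trial(obs, models, nul, "median"))
})

test_that("lowering the best distance never flips a model label to RANDOM", {
  models <- lateral_models()
  nul <- fake_null(mu = 12, sd_uniform = 4, sd_normal = 4, q20 = 8)
  pi_poly <- models$PI$polyline
  perp <- c(-sin(pi / 4), cos(pi / 4))
  labels <- vapply(seq(14, 0.5, by = -1.5), function(off) {
    obs <- trajectory("t", "f", 0:1, pi_poly[, 1] + off * perp[1],
                      pi_poly[, 2] + off * perp[2])
    classify_trial(obs, models, nul, "sd_uniform")$label
  }, character(1))
  # once a model label appears it persists as distance decreases
  first_model <- match(TRUE, labels != "RANDOM")
  expect_false(is.na(first_model))
  expect_true(all(labels[first_model:length(labels)] == labels[first_model]))
})

test_that("uniform-heading swimmers are mostly labelled RANDOM", {
  # specificity of the mu - SD_uniform rule on straight-ish random swimmers
  models <- lateral_models()
  door <- displaced_chamber_position(default_config, "lateral")
  sp <- synthetic_spec()
  n <- 40
  lab <- character(n)
  for (i in seq_len(n)) {
    sim <- suppressMessages(simulate_trajectory(
      "RANDOM", "lateral", default_config, sp, seed = 20100 + i))
    cr <- crop_at_turnback(sim$trajectory, door)
    nul <- build_null(cr$trajectory, models$PI, n = 5000, seed = 20200 + i)
    lab[i] <- classify_trial(cr$trajectory, models, nul)$label
  }
  expect_gte(mean(lab == "RANDOM"), 0.70)
})
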