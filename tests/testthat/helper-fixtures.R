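# Shared fixtures: all built in code, no stored data.

default_config <- arena_config()

lateral_models <- function(config = default_config) {
  stats::setNames(
    lapply(c("PI", "APC", "RR"), function(s)
      build_model_trajectory(config, s, "lateral")),
    c("PI", "APC", "RR"))
}

# straight-line trajectory at a heading (deg, y-down frame), 1 Hz, unit steps
straight_traj <- function(heading_deg, n = 10, step = 1, start = c(0, 0),
                          trial_id = "t", fish_id = "f") {
  th <- heading_deg * pi / 180
  k <- 0:(n - 1)
  trajectory(trial_id, fish_id, t = k,
             x = start[1] + k * step * cos(th),
             y = start[2] + k * step * sin(th))
}

# trajectory built from a sequence of per-step headings (deg)
headings_traj <- function(headings_deg, step = 1, start = c(0, 0),
                          trial_id = "t", fish_id = "f") {
  th <- headings_deg * pi / 180
  x <- start[1] + cumsum(c(0, step * cos(th)))
  y <- start[2] + cumsum(c(0, step * sin(th)))
  trajectory(trial_id, fish_id, t = seq_along(x) - 1, x = x, y = y)
}

# synthetic null_distribution with chosen summary values (for rule tests)
fake_null <- function(mu, sd_uniform = 0, sd_normal = sd_uniform, q20 = mu) {
  structure(list(mean_distances = numeric(0), mu = mu,
                 a = mu - sd_uniform * sqrt(3), b = mu + sd_uniform * sqrt(3),
                 sd_uniform = sd_uniform, sd_normal = sd_normal, q20 = q20,
                 n = 0L, seed = NA_integer_),
            class = "null_distribution")
}

axial_from_doubled <- function(th_rad) (th_rad * 90 / pi) %% 180
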