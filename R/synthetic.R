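#' Specification for a synthetic cohort
#'
#' Defines the study conditions emulated by the generator: 1 Hz sampling
#' from the displaced chamber door, strategy-following swimmers tracking
#' their model polyline with von Mises heading noise and normally
#' distributed step lengths, a scripted turn-back toward the chamber, and
#' uniform-heading random swimmers. Default strategy frequencies follow the
#' observed cohort composition (8 PI : 6 APC : 5 RR : 16 random); default
#' speeds give the few-cm/s swimming typical of these trials.
#'
#' @param n_fish Number of fish.
#' @param trials_per_fish 1 or 2 trials per fish (two displacements).
#' @param strategy_probs Named probabilities over PI, APC, RR, RANDOM;
#'   must sum to 1.
#' @param heading_noise_kappa von Mises concentration of per-step heading
#'   noise (larger = straighter).
#' @param speed_mean,speed_sd Mean and SD of the per-step speed (cm/s).
#' @param turnback_after Fraction of the model-path length after which a
#'   strategy swimmer turns back toward the chamber.
#' @param age_range Uniform range for fish age (days).
#' @param strategy_coefs Optional multinomial-logit coefficient list for
#'   covariate-dependent strategy assignment (see
#'   [simulate_cohort()]); `NULL` draws strategies from `strategy_probs`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_fish = 40, trials_per_fish = 2,
                           strategy_probs = c(PI = 8, APC = 6, RR = 5,
                                              RANDOM = 16) / 35,
                           heading_noise_kappa = 50,
                           speed_mean = 3, speed_sd = 1,
                           turnback_after = 1,
                           age_range = c(365, 1460),
                           strategy_coefs = NULL) {
  if (abs(sum(strategy_probs) - 1) > 1e-8)
    stop_named("contract_error", "strategy_probs must sum to 1")
  if (!all(c("PI", "APC", "RR", "RANDOM") %in% names(strategy_probs)))
    stop_named("contract_error",
               "strategy_probs needs PI, APC, RR, RANDOM entries")
  if (heading_noise_kappa < 0)
    stop_named("contract_error", "kappa must be >= 0")
  if (speed_mean <= 0 || speed_sd < 0)
    stop_named("contract_error", "speeds must be positive")
  structure(list(n_fish = n_fish, trials_per_fish = trials_per_fish,
                 strategy_probs = strategy_probs,
                 heading_noise_kappa = heading_noise_kappa,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 turnback_after = turnback_after, age_range = age_range,
                 strategy_coefs = strategy_coefs),
            class = "synthetic_spec")
}

# point on the polyline at arc distance s along it (clamped to the ends)
polyline_point_at <- function(poly, s) {
  cs <- cum_arc(poly)
  s <- min(max(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(poly) - 1L)
  frac <- if (cs[i + 1] > cs[i]) (s - cs[i]) / (cs[i + 1] - cs[i]) else 0
  poly[i, ] + frac * (poly[i + 1, ] - poly[i, ])
}

reflect_into <- function(p, side) {
  # reflective boundary: fold coordinates back into [0, side]
  hit <- FALSE
  for (j in 1:2) {
    folds <- 0L
    while (p[j] < 0 || p[j] > side) {
      if (p[j] < 0) p[j] <- -p[j]
      if (p[j] > side) p[j] <- 2 * side - p[j]
      folds <- folds + 1L
      if (folds > 10L)
        stop_named("rejected_spec",
                   "step length incompatible with the tank size")
    }
    hit <- hit || folds > 0L
  }
  attr(p, "reflected") <- hit
  p
}

#' Simulate one trial trajectory with known ground truth
#'
#' Strategy trials (PI, APC, RR) follow the model polyline: at each 1 Hz
#' step the swimmer aims at the point the model path reaches after that
#' step's arc progress, with the aim perturbed by von Mises noise of
#' concentration `heading_noise_kappa` and step length drawn from
#' Normal(`speed_mean`, `speed_sd`) truncated at 0.1 cm (so the noiseless
#' limit lies on the polyline exactly). After
#' `turnback_after` times the model length the swimmer turns back toward
#' the chamber door (scripted, so the turn-back sample index is known
#' ground truth). RANDOM trials draw one heading uniformly on \[0, 360) and
#' follow it as a correlated walk with the same heading noise, without a
#' scripted turn-back. Positions are reflected at the tank walls.
#'
#' @param strategy `"PI"`, `"APC"`, `"RR"` or `"RANDOM"`.
#' @param displacement `"lateral"` or `"diagonal"`.
#' @param config An [arena_config()].
#' @param spec A [synthetic_spec()].
#' @param trial_id,fish_id Identifiers.
#' @param seed Optional seed.
#' @return List with `trajectory` (`fish_trajectory`, `analysis_window`
#'   + 1 samples) and `truth` (data.frame: trial_id, fish_id, strategy,
#'   displacement, turn_index).
#' @export
simulate_trajectory <- function(strategy, displacement, config, spec,
                                trial_id = "t1", fish_id = "f1",
                                seed = NULL) {
  if (!strategy %in% c("PI", "APC", "RR", "RANDOM"))
    stop_named("config_error", "unknown strategy '%s'", strategy)
  check_displacement(displacement)
  door <- displaced_chamber_position(config, displacement)
  n_steps <- config$analysis_window
  kappa <- spec$heading_noise_kappa
  with_seed(seed, {
    pos <- door
    xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
    xs[1] <- pos[1]; ys[1] <- pos[2]
    turn_index <- NA_integer_
    if (strategy == "RANDOM") {
      heading <- stats::runif(1, 0, 360)
      poly <- NULL; turn_at <- Inf
    } else {
      model <- build_model_trajectory(config, strategy, displacement)
      poly <- model$polyline
      turn_at <- model$total_length * spec$turnback_after
      heading <- NA_real_
    }
    travelled <- 0
    returning <- FALSE
    n_reflect <- 0L
    for (i in seq_len(n_steps)) {
      step <- max(0.1, stats::rnorm(1, spec$speed_mean, spec$speed_sd))
      move <- step
      if (is.null(poly)) {
        target <- heading   # correlated walk about the previous heading
      } else if (returning) {
        to_door <- sqrt(sum((door - pos)^2))
        move <- min(step, max(to_door, 0.1))
        target <- if (to_door > 1e-9)
          seg_heading(pos[1], pos[2], door[1], door[2]) else 0
      } else {
        # aim at the point the model path reaches after this step's arc
        # progress; steps are capped at polyline vertices (the fish slows
        # into the turn), so the noiseless limit lies on the polyline
        # exactly, corner sample included
        s_next <- min(travelled + step, turn_at)
        cs <- cum_arc(poly)
        inner <- cs[-c(1, length(cs))]
        ahead <- inner[inner > travelled + 1e-9]
        if (length(ahead) && s_next > ahead[1]) s_next <- ahead[1]
        tp <- polyline_point_at(poly, s_next)
        move <- sqrt(sum((tp - pos)^2))
        target <- if (move > 1e-9)
          seg_heading(pos[1], pos[2], tp[1], tp[2]) else 0
        if (s_next >= turn_at - 1e-9) {
          returning <- TRUE
          turn_index <- i + 1L   # first sample of the return phase
        }
        step <- s_next - travelled   # arc progress actually scheduled
      }
      noise <- if (!is.finite(kappa)) 0
               else if (kappa > 0) rad2deg(rvonmises(1, 0, kappa))
               else stats::runif(1, 0, 360)
      noise <- ((noise + 180) %% 360) - 180
      heading <- (target + noise) %% 360
      pos <- pos + move * unit_vec(heading)
      pos <- reflect_into(pos, config$tank_side)
      n_reflect <- n_reflect + isTRUE(attr(pos, "reflected"))
      attr(pos, "reflected") <- NULL
      travelled <- travelled + step
      xs[i + 1] <- pos[1]; ys[i + 1] <- pos[2]
    }
    if (n_reflect > 0)
      message(sprintf("trial %s: reflective boundary applied at %d step(s)",
                      trial_id, n_reflect))
    traj <- trajectory(trial_id, fish_id, 0:n_steps, xs, ys,
                       tank_side = config$tank_side)
    list(trajectory = traj,
         truth = data.frame(trial_id = trial_id, fish_id = fish_id,
                            strategy = strategy, displacement = displacement,
                            turn_index = turn_index,
                            stringsAsFactors = FALSE))
  })
}

# multinomial-logit strategy assignment given covariates; coefs is a list
# with one named numeric vector per non-reference strategy, terms
# (intercept, age, swim_speed, displacement_diagonal, trial_number)
assign_strategy <- function(spec, age, speed, displacement, trial_number) {
  if (is.null(spec$strategy_coefs)) {
    return(sample(names(spec$strategy_probs), 1,
                  prob = spec$strategy_probs))
  }
  x <- c(1, age, speed, as.numeric(displacement == "diagonal"), trial_number)
  eta <- vapply(spec$strategy_coefs, function(b) sum(b * x), numeric(1))
  p <- exp(c(RANDOM = 0, eta))
  p <- p / sum(p)
  sample(names(p), 1, prob = p)
}

#' Simulate a full cohort with ground truth
#'
#' Each fish receives covariates (age uniform over `age_range`, per-fish
#' swim speed Normal(`speed_mean`, `speed_sd`) truncated at 0.5 cm/s) and
#' `trials_per_fish` trials alternating lateral/diagonal displacement (half
#' the cohort starts with each, as in the counterbalanced design). Strategy
#' is drawn per trial from `strategy_probs`, or from a multinomial logit on
#' the covariates when `strategy_coefs` is supplied.
#'
#' @param spec A [synthetic_spec()].
#' @param config An [arena_config()].
#' @param seed Optional seed.
#' @param out_dir Optional directory; when given, writes
#'   `trajectories.csv`, `metadata.csv` and `truth.csv`.
#' @return List with `trajectories` (named list of `fish_trajectory`),
#'   `metadata` (data.frame: trial_id, fish_id, age, swim_speed,
#'   displacement, trial_number) and `truth` (data.frame with the
#'   generating strategy and turn index per trial).
#' @export
simulate_cohort <- function(spec, config = arena_config(), seed = NULL,
                            out_dir = NULL) {
  if (spec$n_fish < 1)
    stop_named("contract_error", "empty cohort")
  with_seed(seed, {
    trajs <- list(); meta <- list(); truth <- list()
    k <- 0L
    for (f in seq_len(spec$n_fish)) {
      fish_id <- sprintf("f%02d", f)
      age <- round(stats::runif(1, spec$age_range[1], spec$age_range[2]))
      speed <- max(0.5, stats::rnorm(1, spec$speed_mean, spec$speed_sd))
      first_disp <- if (f %% 2 == 1) "lateral" else "diagonal"
      for (tr in seq_len(spec$trials_per_fish)) {
        k <- k + 1L
        displacement <- if (tr %% 2 == 1) first_disp else
          setdiff(c("lateral", "diagonal"), first_disp)
        trial_id <- sprintf("%s_T%d", fish_id, tr)
        strat <- assign_strategy(spec, age, speed, displacement, tr)
        fish_spec <- spec
        fish_spec$speed_mean <- speed
        sim <- simulate_trajectory(strat, displacement, config, fish_spec,
                                   trial_id = trial_id, fish_id = fish_id)
        trajs[[trial_id]] <- sim$trajectory
        truth[[trial_id]] <- sim$truth
        meta[[trial_id]] <- data.frame(
          trial_id = trial_id, fish_id = fish_id, age = age,
          swim_speed = speed, displacement = displacement,
          trial_number = tr, stringsAsFactors = FALSE)
      }
    }
    out <- list(trajectories = trajs,
                metadata = do.call(rbind, meta),
                truth = do.call(rbind, truth))
    rownames(out$metadata) <- rownames(out$truth) <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_trajectories(out$trajectories,
                         file.path(out_dir, "trajectories.csv"))
      utils::write.csv(out$metadata, file.path(out_dir, "metadata.csv"),
                       row.names = FALSE)
      utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
    }
    out
  })
}
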