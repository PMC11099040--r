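#' Arena geometry configuration
#'
#' Encodes the square experimental tank, the reward-chamber door where every
#' homing trajectory starts, the home-shell and L-tunnel geometry used by the
#' synthetic generator, and the two passive displacement vectors. All
#' coordinates are in cm, with the origin at the tank's top-left corner,
#' x increasing rightward and y increasing downward (the overhead-camera
#' pixel convention, so "0.5 m to the right, 0.5 m down" is a positive
#' vector).
#'
#' @param tank_side Side length of the square tank (cm).
#' @param chamber_origin Centre of the reward-chamber door before
#'   displacement (cm, length-2 numeric), at the end of the L-tunnel.
#' @param chamber_diameter Reward chamber diameter (cm).
#' @param door_diameter Sliding door diameter (cm).
#' @param shell_position Home-shell position (cm), used by the synthetic
#'   generator only.
#' @param tunnel_leg Length of each of the two equal legs of the L-shaped
#'   tunnel (cm).
#' @param tunnel_diameter Tunnel diameter (cm).
#' @param displacement_lateral Lateral displacement vector (cm).
#' @param displacement_diagonal Diagonal displacement vector (cm); its norm
#'   is ~70.7 cm (0.71 m right-down).
#' @param analysis_window Number of seconds of trajectory analysed after the
#'   fish exits the chamber.
#' @param turnback_cone_deg Half-angle of the turn-back detection cone
#'   (degrees).
#' @param turnback_persistence Number of consecutive chamber-ward steps that
#'   triggers the turn-back crop.
#' @return An object of class `arena_config`.
#' @examples
#' cfg <- arena_config()
#' displaced_chamber_position(cfg, "lateral")
#' @export
arena_config <- function(tank_side = 130,
                         chamber_origin = c(40, 15),
                         chamber_diameter = 9.5,
                         door_diameter = 6.5,
                         shell_position = c(12, 12),
                         tunnel_leg = 30,
                         tunnel_diameter = 7,
                         displacement_lateral = c(50, 0),
                         displacement_diagonal = c(50, 50),
                         analysis_window = 60,
                         turnback_cone_deg = 30,
                         turnback_persistence = 2) {
  cfg <- list(tank_side = tank_side,
              chamber_origin = as.numeric(chamber_origin),
              chamber_diameter = chamber_diameter,
              door_diameter = door_diameter,
              shell_position = as.numeric(shell_position),
              tunnel_leg = tunnel_leg,
              tunnel_diameter = tunnel_diameter,
              displacement_lateral = as.numeric(displacement_lateral),
              displacement_diagonal = as.numeric(displacement_diagonal),
              analysis_window = analysis_window,
              turnback_cone_deg = turnback_cone_deg,
              turnback_persistence = turnback_persistence)
  validate_arena_config(cfg)
  structure(cfg, class = "arena_config")
}

validate_arena_config <- function(cfg) {
  if (cfg$tank_side <= 0)
    stop_named("config_error", "tank_side must be positive")
  for (nm in c("chamber_origin", "shell_position")) {
    p <- cfg[[nm]]
    if (length(p) != 2 || any(!is.finite(p)) || any(p < 0) ||
        any(p > cfg$tank_side))
      stop_named("config_error", "%s must lie inside the tank square", nm)
  }
  if (length(cfg$displacement_lateral) != 2 ||
      length(cfg$displacement_diagonal) != 2)
    stop_named("config_error", "displacement vectors must have length 2")
  invisible(cfg)
}

#' Read an arena configuration from a YAML file
#'
#' Fields absent from the file keep their [arena_config()] defaults.
#'
#' @param path Path to a YAML file whose keys are `arena_config()` arguments.
#' @return An `arena_config` object.
#' @export
read_arena_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(arena_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_named("config_error", "unknown arena config fields: %s",
               paste(bad, collapse = ", "))
  do.call(arena_config, vals)
}

#' Printed model expectations per strategy and displacement
#'
#' The expected first orientation angle, start-to-end angle and travel
#' distance for each navigational strategy under each displacement. These are
#' the constants the group-level tests are run against; model trajectories
#' are constructed from them.
#'
#' @return A data.frame with columns `strategy`, `displacement`,
#'   `expected_first_angle_deg`, `expected_start_end_angle_deg`,
#'   `expected_length_cm`.
#' @export
strategy_expectations <- function() {
  data.frame(
    strategy = c("PI", "PI", "APC", "APC", "RR", "RR"),
    displacement = c("lateral", "diagonal", "lateral", "diagonal",
                     "lateral", "diagonal"),
    expected_first_angle_deg = c(45, 45, 135, 180, 90, 90),
    expected_start_end_angle_deg = c(45, 45, 135, 180, 45, 45),
    expected_length_cm = c(38.6, 38.6, 38.6, 27.3, 54.5, 54.5),
    stringsAsFactors = FALSE
  )
}

check_strategy <- function(strategy) {
  if (!is.character(strategy) || length(strategy) != 1 ||
      !strategy %in% c("PI", "APC", "RR"))
    stop_named("config_error", "unknown strategy '%s'", paste(strategy, collapse = ","))
  strategy
}

check_displacement <- function(displacement) {
  if (!is.character(displacement) || length(displacement) != 1 ||
      !displacement %in% c("lateral", "diagonal"))
    stop_named("config_error", "unknown displacement '%s'",
               paste(displacement, collapse = ","))
  displacement
}

#' Position of the displaced reward chamber
#'
#' @param config An [arena_config()].
#' @param displacement `"lateral"` or `"diagonal"`.
#' @return Length-2 numeric, the displaced chamber-door centre (cm).
#' @export
displaced_chamber_position <- function(config, displacement) {
  check_displacement(displacement)
  vec <- switch(displacement,
                lateral = config$displacement_lateral,
                diagonal = config$displacement_diagonal)
  pos <- config$chamber_origin + vec
  margin <- config$chamber_diameter / 2
  if (any(pos < margin) || any(pos > config$tank_side - margin))
    stop_named("geometry_error",
               "displaced chamber at (%.1f, %.1f) is outside the tank",
               pos[1], pos[2])
  pos
}

#' Construct a model trajectory
#'
#' Builds the predicted homing polyline for one strategy under one
#' displacement, anchored at the displaced chamber door. Path-integration
#' (PI) and allothetic-place-cue (APC) predictions are straight segments at
#' the expected angle and length; route recapitulation (RR) is two equal
#' right-angle legs mirroring the L-tunnel (first leg at the expected RR
#' first angle, 54.5/2 cm each), whose start-to-end chord subtends 45
#' degrees.
#'
#' @param config An [arena_config()].
#' @param strategy `"PI"`, `"APC"` or `"RR"`.
#' @param displacement `"lateral"` or `"diagonal"`.
#' @return An object of class `model_trajectory` with fields `strategy`,
#'   `displacement`, `polyline` (matrix of x, y in cm) and `total_length`.
#' @examples
#' m <- build_model_trajectory(arena_config(), "PI", "lateral")
#' m$total_length  # 38.6
#' @export
build_model_trajectory <- function(config, strategy, displacement) {
  check_strategy(strategy)
  check_displacement(displacement)
  exp_tab <- strategy_expectations()
  row <- exp_tab[exp_tab$strategy == strategy &
                   exp_tab$displacement == displacement, ]
  start <- displaced_chamber_position(config, displacement)
  if (strategy %in% c("PI", "APC")) {
    end <- start + row$expected_length_cm * unit_vec(row$expected_first_angle_deg)
    poly <- rbind(start, end)
  } else {
    # RR: two legs of equal length; first at the expected first angle, the
    # second turned 90 degrees so the chord subtends the start-end angle.
    leg <- row$expected_length_cm / 2
    p1 <- start + leg * unit_vec(row$expected_first_angle_deg)
    p2 <- p1 + leg * unit_vec(row$expected_first_angle_deg - 90)
    poly <- rbind(start, p1, p2)
  }
  dimnames(poly) <- list(NULL, c("x", "y"))
  structure(list(strategy = strategy, displacement = displacement,
                 polyline = poly,
                 total_length = arc_length(poly)),
            class = "model_trajectory")
}

#' @export
print.model_trajectory <- function(x, ...) {
  cat(sprintf("<model_trajectory %s/%s: %d vertices, %.2f cm>\n",
              x$strategy, x$displacement, nrow(x$polyline), x$total_length))
  invisible(x)
}
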