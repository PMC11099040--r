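#' Construct a fish trajectory
#'
#' A trajectory is the 1 Hz digitised path of one fish in one trial:
#' strictly increasing timestamps (s) and x/y positions (cm) in the tank
#' frame.
#'
#' @param trial_id,fish_id Identifiers (scalars, coerced to character).
#' @param t,x,y Equal-length numeric vectors: time (s) and position (cm).
#' @param tank_side Optional tank side (cm) for the in-tank check; `NULL`
#'   skips it.
#' @return An object of class `fish_trajectory`.
#' @export
trajectory <- function(trial_id, fish_id, t, x, y, tank_side = NULL) {
  if (length(t) != length(x) || length(t) != length(y))
    stop_named("validation_error", "trial %s: t, x, y lengths differ", trial_id)
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop_named("validation_error", "trial %s: non-finite sample values", trial_id)
  if (length(t) >= 2 && any(diff(t) <= 0))
    stop_named("validation_error", "trial %s: time not strictly increasing", trial_id)
  if (!is.null(tank_side) &&
      (any(x < 0 | x > tank_side) || any(y < 0 | y > tank_side)))
    stop_named("validation_error", "trial %s: coordinates outside the tank", trial_id)
  structure(list(trial_id = as.character(trial_id),
                 fish_id = as.character(fish_id),
                 t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
            class = "fish_trajectory")
}

#' @export
print.fish_trajectory <- function(x, ...) {
  cat(sprintf("<fish_trajectory %s (fish %s): %d samples, %.1f s, %.1f cm>\n",
              x$trial_id, x$fish_id, length(x$t), diff(range(x$t)),
              arc_length(traj_points(x))))
  invisible(x)
}

traj_points <- function(traj) cbind(x = traj$x, y = traj$y)

traj_subset <- function(traj, idx) {
  trajectory(traj$trial_id, traj$fish_id, traj$t[idx], traj$x[idx], traj$y[idx])
}

#' Read trajectories from CSV
#'
#' Expects a header `trial_id,fish_id,t_s,x_cm,y_cm`; rows are grouped by
#' `trial_id` and time-sorted. Validation failures name the offending trial
#' and line numbers.
#'
#' @param file Path to the CSV.
#' @param tank_side Optional tank side (cm) to validate coordinates against.
#' @return A named list of `fish_trajectory` objects, one per trial.
#' @export
read_trajectories <- function(file, tank_side = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("trial_id", "fish_id", "t_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_named("validation_error", "missing columns: %s",
               paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$t_s) | !is.finite(df$x_cm) | !is.finite(df$y_cm))
  if (length(bad))
    stop_named("validation_error", "malformed rows at lines %s",
               paste(bad + 1L, collapse = ", "))
  out <- lapply(split(df, df$trial_id), function(g) {
    g <- g[order(g$t_s), ]
    if (any(diff(g$t_s) <= 0))
      stop_named("validation_error",
                 "trial %s: time not strictly increasing", g$trial_id[1])
    trajectory(g$trial_id[1], g$fish_id[1], g$t_s, g$x_cm, g$y_cm,
               tank_side = tank_side)
  })
  out[order(names(out))]
}

#' Write trajectories to CSV
#'
#' @param trajs List of `fish_trajectory` objects.
#' @param file Output path.
#' @param crop_index Optional named integer vector (by trial id) recording
#'   where each trajectory was cropped; written as a provenance column.
#' @export
write_trajectories <- function(trajs, file, crop_index = NULL) {
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(trial_id = tr$trial_id, fish_id = tr$fish_id,
               t_s = tr$t, x_cm = tr$x, y_cm = tr$y,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(crop_index))
    rows$crop_index <- unname(crop_index[rows$trial_id])
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Polyline arc length
#'
#' @param points Two-column matrix of ordered (x, y) points (cm).
#' @return Total Euclidean length (cm).
#' @examples
#' arc_length(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
arc_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    stop_named("degenerate_trajectory", "arc_length needs >= 2 points")
  sum(sqrt(rowSums(diff(points)^2)))
}

cum_arc <- function(points) {
  c(0, cumsum(sqrt(rowSums(diff(points)^2))))
}

#' Crop a trajectory at turn-back toward the chamber
#'
#' The trajectory is first truncated to the analysis window, then scanned for
#' the first run of `persistence` consecutive steps that both head to within
#' `cone_deg` of the bearing to the chamber and decrease the distance to it;
#' the returned prefix ends at the last sample before that run. If no such
#' run exists the window-truncated trajectory is returned unchanged.
#'
#' @param traj A `fish_trajectory` with at least 3 samples.
#' @param chamber Length-2 numeric, the displaced chamber-door centre (cm).
#' @param cone_deg Half-angle of the detection cone (degrees).
#' @param persistence Number of consecutive qualifying steps required.
#' @param analysis_window Seconds of trajectory kept after the first sample.
#' @return A list with `trajectory` (the cropped `fish_trajectory`) and
#'   `crop_index` (last retained sample index, `NA` if no turn-back found).
#' @export
crop_at_turnback <- function(traj, chamber, cone_deg = 30, persistence = 2,
                             analysis_window = 60) {
  n <- length(traj$t)
  if (n < 3)
    stop_named("degenerate_trajectory", "trial %s: < 3 samples", traj$trial_id)
  keep <- which(traj$t - traj$t[1] <= analysis_window)
  traj <- traj_subset(traj, keep)
  n <- length(traj$t)
  if (n < 3)
    stop_named("degenerate_trajectory",
               "trial %s: < 3 samples inside the analysis window", traj$trial_id)
  # step i is the move from sample i to sample i+1
  hx <- diff(traj$x); hy <- diff(traj$y)
  head_deg <- (rad2deg(atan2(hy, hx))) %% 360
  bear_deg <- (rad2deg(atan2(chamber[2] - traj$y[-n],
                             chamber[1] - traj$x[-n]))) %% 360
  d_cham <- sqrt((traj$x - chamber[1])^2 + (traj$y - chamber[2])^2)
  qualifies <- ang_diff(head_deg, bear_deg) <= cone_deg &
    d_cham[-1] < d_cham[-n] &
    (hx != 0 | hy != 0)
  run <- 0L; trigger <- NA_integer_
  for (i in seq_along(qualifies)) {
    run <- if (qualifies[i]) run + 1L else 0L
    if (run >= persistence) { trigger <- i - persistence + 1L; break }
  }
  if (is.na(trigger)) {
    return(list(trajectory = traj, crop_index = NA_integer_))
  }
  # step `trigger` moves from sample trigger to trigger+1; keep up to the
  # last sample before the run starts
  last <- trigger
  if (last < 3)
    stop_named("degenerate_trajectory",
               "trial %s: turn-back too early (%d samples)", traj$trial_id, last)
  list(trajectory = traj_subset(traj, seq_len(last)), crop_index = last)
}

#' Truncate a polyline to a given arc length
#'
#' The last partial segment is linearly interpolated so the result's arc
#' length equals `target` exactly (within floating point).
#'
#' @param points Two-column (x, y) matrix.
#' @param target Target arc length (cm); must not exceed the polyline length.
#' @return Truncated (x, y) matrix.
#' @export
truncate_to_length <- function(points, target) {
  points <- as.matrix(points)
  s <- cum_arc(points)
  total <- s[length(s)]
  if (target <= 0)
    stop_named("degenerate_trajectory", "target length must be positive")
  if (target >= total) return(points)
  i <- max(which(s < target))   # last vertex strictly before the cut
  frac <- (target - s[i]) / (s[i + 1] - s[i])
  cut <- points[i, ] + frac * (points[i + 1, ] - points[i, ])
  out <- rbind(points[seq_len(i), , drop = FALSE], cut)
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Crop two paths to a common arc length
#'
#' The longer path is truncated (last partial segment interpolated) so both
#' have arc length `min(L_a, L_b)`.
#'
#' @param a,b Two-column (x, y) matrices with positive arc length.
#' @return A list with elements `a`, `b` (matrices) and `length` (cm).
#' @export
crop_to_common_length <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  la <- arc_length(a); lb <- arc_length(b)
  if (la <= 0 || lb <= 0)
    stop_named("degenerate_trajectory", "zero-length path")
  L <- min(la, lb)
  list(a = truncate_to_length(a, L), b = truncate_to_length(b, L), length = L)
}

# Modified-Akima (makima) node slopes, MATLAB convention: secant slopes are
# extrapolated quadratically at the ends and the Akima weights gain the
# |mean| term that tames oscillation on flat data.
makima_slopes <- function(h, delta) {
  m <- length(delta)
  # pad two extrapolated secants at each end
  dm1 <- 2 * delta[1] - delta[min(2, m)]
  dm2 <- 2 * dm1 - delta[1]
  dp1 <- 2 * delta[m] - delta[max(1, m - 1)]
  dp2 <- 2 * dp1 - delta[m]
  d <- c(dm2, dm1, delta, dp1, dp2)
  n <- m + 1                            # number of nodes
  t <- numeric(n)
  for (i in seq_len(n)) {
    # node i sits between padded secants d[i+1] (left) and d[i+2] (right)
    dl2 <- d[i]; dl1 <- d[i + 1]; dr1 <- d[i + 2]; dr2 <- d[i + 3]
    w1 <- abs(dr2 - dr1) + abs(dr2 + dr1) / 2
    w2 <- abs(dl1 - dl2) + abs(dl1 + dl2) / 2
    t[i] <- if (w1 + w2 == 0) 0 else (w1 * dl1 + w2 * dr1) / (w1 + w2)
  }
  t
}

# Evaluate the makima piecewise-cubic Hermite interpolant of (xs, ys) at xq.
makima_eval <- function(xs, ys, xq) {
  m <- length(xs) - 1
  if (m == 0) return(rep(ys, length(xq)))
  h <- diff(xs)
  delta <- diff(ys) / h
  t <- if (m == 1) rep(delta, 2) else makima_slopes(h, delta)
  i <- findInterval(xq, xs, rightmost.closed = TRUE)
  i[i < 1] <- 1; i[i > m] <- m
  s <- (xq - xs[i]) / h[i]
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * ys[i] + h10 * h[i] * t[i] + h01 * ys[i + 1] + h11 * h[i] * t[i + 1]
}

#' Resample a path to 1000 evenly spaced points
#'
#' x and y are each fitted with a modified-Akima (shape-preserving
#' piecewise-cubic) interpolant against cumulative arc length, then sampled
#' at `n` stations equally spaced along that arc length. With two knots the
#' scheme reduces to linear interpolation.
#'
#' @param points Two-column (x, y) matrix with at least 2 distinct points.
#' @param n Number of output points (default 1000).
#' @return An object of class `interp_path`: list with `points` (n x 2
#'   matrix) and `source_length` (cm).
#' @export
interpolate_1000 <- function(points, n = 1000) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    stop_named("degenerate_trajectory", "need >= 2 points to interpolate")
  s <- cum_arc(points)
  # drop (near-)coincident consecutive points: they carry no shape
  # information and destabilise the slope weights
  keep <- c(TRUE, diff(s) > 1e-9)
  points <- points[keep, , drop = FALSE]
  s <- s[keep]
  if (nrow(points) < 2)
    stop_named("degenerate_trajectory", "all points identical")
  stations <- seq(0, s[length(s)], length.out = n)
  out <- cbind(x = makima_eval(s, points[, 1], stations),
               y = makima_eval(s, points[, 2], stations))
  structure(list(points = out, source_length = s[length(s)]),
            class = "interp_path")
}

#' Resample a polyline exactly at equal arc-length stations
#'
#' Unlike [interpolate_1000()], no smoothing is applied: every output point
#' lies on the input polyline. Used for model trajectories, which are exact
#' geometric predictions (smoothing would round the route-recapitulation
#' right angle into a bulge of several cm).
#'
#' @param points Two-column (x, y) matrix with >= 2 distinct points.
#' @param n Number of output points (default 1000).
#' @return An `interp_path` object.
#' @export
resample_polyline <- function(points, n = 1000) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    stop_named("degenerate_trajectory", "need >= 2 points to resample")
  s <- cum_arc(points)
  keep <- c(TRUE, diff(s) > 1e-9)
  points <- points[keep, , drop = FALSE]
  s <- s[keep]
  if (nrow(points) < 2)
    stop_named("degenerate_trajectory", "all points identical")
  stations <- seq(0, s[length(s)], length.out = n)
  out <- cbind(x = stats::approx(s, points[, 1], xout = stations)$y,
               y = stats::approx(s, points[, 2], xout = stations)$y)
  structure(list(points = out, source_length = s[length(s)]),
            class = "interp_path")
}

#' Pointwise distances between two interpolated paths
#'
#' @param a,b `interp_path` objects with the same number of points.
#' @return A list with `distances` (vector of per-index Euclidean distances,
#'   cm) and `mean` (their arithmetic mean).
#' @export
pointwise_distances <- function(a, b) {
  pa <- if (inherits(a, "interp_path")) a$points else as.matrix(a)
  pb <- if (inherits(b, "interp_path")) b$points else as.matrix(b)
  if (nrow(pa) != nrow(pb))
    stop_named("contract_error", "paths have different numbers of points")
  d <- sqrt((pa[, 1] - pb[, 1])^2 + (pa[, 2] - pb[, 2])^2)
  list(distances = d, mean = mean(d))
}
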