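#' Standard deviation of a continuous uniform distribution
#'
#' @param a,b Interval endpoints, `b >= a`.
#' @return `(b - a) / sqrt(12)`.
#' @examples
#' sd_uniform(0, 12)  # 3.4641
#' @export
sd_uniform <- function(a, b) {
  if (b < a) stop_named("contract_error", "sd_uniform needs b >= a")
  (b - a) / sqrt(12)
}

#' Generate one random straight trajectory
#'
#' A straight 2-vertex polyline from `start` at a heading drawn uniformly on
#' \[0, 180) degrees, of the given arc length. This is the building block of
#' the random-trajectory null.
#'
#' @param length Arc length (cm), positive.
#' @param start Length-2 numeric start point (cm).
#' @return Two-row (x, y) matrix.
#' @export
generate_random_trajectory <- function(length, start = c(0, 0)) {
  if (!is.finite(length) || length <= 0)
    stop_named("contract_error", "length must be positive")
  theta <- stats::runif(1, 0, 180)
  out <- rbind(start, start + length * unit_vec(theta))
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Build the random-trajectory null distribution
#'
#' For `n` random straight trajectories (headings uniform on \[0, 180),
#' anchored at the observed trajectory's start, each of arc length equal to
#' the smaller of the observed and PI-model lengths), the observed trajectory
#' and each random trajectory are cropped to common length, interpolated to
#' 1000 points, and the mean pointwise Euclidean distance recorded. The
#' 10,000 means are summarised by the fitted-uniform interval \[a, b\]
#' (sample min/max), `sd_uniform = (b - a)/sqrt(12)`, the sample SD
#' (`sd_normal`) and the 20th percentile of the empirical CDF (`q20`).
#'
#' @param observed A cropped `fish_trajectory`, or a two-column (x, y)
#'   matrix.
#' @param pi_model The PI `model_trajectory` for the trial's displacement
#'   (fixes the null trajectory length).
#' @param n Number of random trajectories (default 10000).
#' @param seed Optional integer seed for a self-contained RNG stream.
#' @return An object of class `null_distribution` with fields
#'   `mean_distances`, `mu`, `a`, `b`, `sd_uniform`, `sd_normal`, `q20`,
#'   `n`, `seed`.
#' @export
build_null <- function(observed, pi_model, n = 10000, seed = NULL) {
  if (!is.numeric(n) || n <= 0)
    stop_named("contract_error", "n must be positive")
  n <- as.integer(n)
  if (n < 100)
    warning("null distribution built from fewer than 100 random trajectories")
  pts <- if (inherits(observed, "fish_trajectory")) traj_points(observed)
         else as.matrix(observed)
  L <- min(arc_length(pts), pi_model$total_length)
  obs_cut <- truncate_to_length(pts, L)
  obs_ip <- interpolate_1000(obs_cut)
  start <- pts[1, ]
  # Random trajectories are straight, so their 1000 interpolated points are
  # the stations r_k * u(theta); the observed interpolation is shared by all
  # draws because common length is min(L_obs, L_PI) for every draw.
  r <- seq(0, L, length.out = 1000)
  ox <- obs_ip$points[, 1] - start[1]
  oy <- obs_ip$points[, 2] - start[2]
  thetas <- with_seed(seed, stats::runif(n, 0, 180))
  th <- deg2rad(thetas)
  ct <- cos(th); st <- sin(th)
  # mean_i = mean_k sqrt((ox_k - r_k ct_i)^2 + (oy_k - r_k st_i)^2)
  o2 <- ox^2 + oy^2
  means <- numeric(n)
  chunk <- 2000L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    cc <- ct[lo:hi]; ss <- st[lo:hi]
    d2 <- tcrossprod(rep(1, hi - lo + 1L), o2 + r^2) -
      2 * (outer(cc, ox * r) + outer(ss, oy * r))
    d2[d2 < 0] <- 0
    means[lo:hi] <- rowMeans(sqrt(d2))
  }
  a <- min(means); b <- max(means)
  structure(list(mean_distances = means,
                 mu = mean(means), a = a, b = b,
                 sd_uniform = sd_uniform(a, b),
                 sd_normal = stats::sd(means),
                 q20 = unname(stats::quantile(means, 0.20, type = 7)),
                 n = n, seed = seed %||% NA_integer_),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(paste0("<null_distribution n=%d: mu=%.2f [a=%.2f, b=%.2f] ",
                     "sd_unif=%.2f sd_norm=%.2f q20=%.2f>\n"),
              x$n, x$mu, x$a, x$b, x$sd_uniform, x$sd_normal, x$q20))
  invisible(x)
}

# mean pointwise distance of an observed path to one model trajectory,
# after cropping both to common length and interpolating to 1000 points.
# The observed (digitized) path gets the makima fit; the model polyline is
# an exact geometric prediction and is resampled without smoothing.
model_distance <- function(obs_pts, model) {
  cc <- crop_to_common_length(obs_pts, model$polyline)
  pointwise_distances(interpolate_1000(cc$a), resample_polyline(cc$b))
}

# moving-block bootstrap CI for the mean of a serially dependent vector
block_boot_ci <- function(d, block = 50, reps = 1000, conf = 0.95) {
  n <- length(d)
  nb <- ceiling(n / block)
  starts_max <- n - block + 1
  means <- vapply(seq_len(reps), function(r) {
    s <- sample.int(starts_max, nb, replace = TRUE)
    idx <- as.vector(outer(0:(block - 1), s, `+`))[seq_len(n)]
    mean(d[idx])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha)))
}

#' Rank model trajectories by similarity to an observed trajectory
#'
#' For each candidate model trajectory, both paths are cropped to common
#' length, interpolated to 1000 points, and the mean pointwise distance
#' computed. Strategies are ranked ascending; exact ties (within 1e-9 cm)
#' are broken in PI > APC > RR priority with a message. Pairwise mean
#' differences carry a moving-block bootstrap interval over the 1000 point
#' indices (block 50, 1000 resamples), accounting for the serial dependence
#' of interpolated distances.
#'
#' @param observed A `fish_trajectory` or (x, y) matrix.
#' @param models Named list of `model_trajectory` objects (names PI, APC,
#'   RR) for the trial's displacement.
#' @param boot Logical; compute the pairwise block-bootstrap contrasts.
#' @param seed Optional seed for the bootstrap.
#' @return List with `ranking` (data.frame strategy/mean_distance),
#'   `distances` (list of 1000-vectors per strategy) and `contrasts`
#'   (data.frame of pairwise mean differences with bootstrap CIs, or NULL).
#' @export
closest_model <- function(observed, models, boot = TRUE, seed = NULL) {
  need <- c("PI", "APC", "RR")
  if (!all(need %in% names(models)))
    stop_named("config_error", "models must include PI, APC and RR")
  pts <- if (inherits(observed, "fish_trajectory")) traj_points(observed)
         else as.matrix(observed)
  res <- lapply(models[need], function(m) model_distance(pts, m))
  mu <- vapply(res, `[[`, numeric(1), "mean")
  prio <- match(need, need)  # PI=1, APC=2, RR=3
  ord <- order(round(mu / 1e-9) * 1e-9, prio)
  if (any(duplicated(round(mu / 1e-9))))
    message("exact tie in mean model distances; PI > APC > RR priority applied")
  ranking <- data.frame(strategy = need[ord], mean_distance = unname(mu[ord]),
                        stringsAsFactors = FALSE)
  contrasts <- NULL
  if (boot) {
    pairs <- utils::combn(need, 2)
    contrasts <- with_seed(seed, do.call(rbind, lapply(
      seq_len(ncol(pairs)), function(j) {
        a <- pairs[1, j]; b <- pairs[2, j]
        dd <- res[[a]]$distances - res[[b]]$distances
        ci <- block_boot_ci(dd)
        data.frame(pair = paste(a, b, sep = "-"), mean_diff = mean(dd),
                   ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
      })))
  }
  list(ranking = ranking,
       distances = lapply(res, `[[`, "distances"),
       contrasts = contrasts)
}

#' Classify one trial against the random-trajectory null
#'
#' The trial is assigned its closest model strategy if the mean distance to
#' that model is below the null threshold, otherwise RANDOM. Thresholds:
#' `sd_uniform` rule, `mu - sd_uniform`; `sd_normal` rule, `mu - sd_normal`;
#' `q20` rule, the 20th percentile of the null CDF.
#'
#' @param observed A cropped `fish_trajectory` or (x, y) matrix.
#' @param models Named list of the three `model_trajectory` objects.
#' @param null A `null_distribution` built for this observed trajectory.
#' @param rule One of `"sd_uniform"`, `"sd_normal"`, `"q20"`.
#' @param trial_id Optional identifier carried into the result.
#' @param seed Optional seed for the ranking bootstrap.
#' @return An object of class `classification_result`.
#' @export
classify_trial <- function(observed, models, null,
                           rule = c("sd_uniform", "sd_normal", "q20"),
                           trial_id = NULL, seed = NULL) {
  rule <- match.arg(rule)
  cm <- closest_model(observed, models, boot = FALSE)
  best <- cm$ranking$strategy[1]
  best_d <- cm$ranking$mean_distance[1]
  threshold <- switch(rule,
                      sd_uniform = null$mu - null$sd_uniform,
                      sd_normal = null$mu - null$sd_normal,
                      q20 = null$q20)
  label <- if (best_d < threshold) best else "RANDOM"
  if (is.null(trial_id) && inherits(observed, "fish_trajectory"))
    trial_id <- observed$trial_id
  structure(list(trial_id = trial_id %||% NA_character_,
                 mean_distance_to = stats::setNames(
                   cm$ranking$mean_distance, cm$ranking$strategy),
                 best_strategy = best, best_distance = best_d,
                 threshold = threshold, rule = rule, label = label,
                 null = list(mu = null$mu, a = null$a, b = null$b,
                             sd_uniform = null$sd_uniform,
                             sd_normal = null$sd_normal, q20 = null$q20,
                             n = null$n, seed = null$seed)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification %s: label=%s (best %s at %.2f cm, threshold %.2f, rule %s)>\n",
              x$trial_id, x$label, x$best_strategy, x$best_distance,
              x$threshold, x$rule))
  invisible(x)
}
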