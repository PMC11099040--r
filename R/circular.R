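# Axial circular statistics. Orientation angles in this experiment live on
# [0, 180) (axial data); all tests and model fits double the angles onto the
# full circle first.

# The printed two-branch arccos formula: with dx = x_end - x1,
# dy = y_end - y1 (y down), theta = acos(dx / r) if dy > 0 (ties resolved to
# this branch) and 360 - acos(dx / r) if dy < 0. Equivalent to
# atan2(dy, dx) mod 360.
branch_angle <- function(x1, y1, xe, ye) {
  dx <- xe - x1; dy <- ye - y1
  r <- sqrt(dx^2 + dy^2)
  if (r == 0)
    stop_named("degenerate_angle", "coincident endpoints")
  base <- rad2deg(acos(pmin(1, pmax(-1, dx / r))))
  if (dy >= 0) base %% 360 else (360 - base) %% 360
}

#' Fold an angle onto the axial domain
#'
#' @param theta_deg Angle(s) in degrees.
#' @return `theta mod 180`, in \[0, 180).
#' @export
axial_fold <- function(theta_deg) theta_deg %% 180

#' First straight-displacement angle of a trajectory
#'
#' Segments are accreted from the first sample while each segment's heading
#' deviates by no more than `max_dev_deg` from the immediately previous
#' segment; the angle is then computed from the first sample to the accreted
#' endpoint with the two-branch arccos formula (equivalently `atan2` in the
#' y-down frame).
#'
#' @param traj A cropped `fish_trajectory` with >= 2 samples.
#' @param max_dev_deg Accretion tolerance between consecutive segment
#'   headings (degrees).
#' @return List with `theta` (degrees in \[0, 360)), `axial` (theta mod
#'   180), `end_index` (last sample of the straight displacement) and
#'   `length` (cm of the accreted displacement).
#' @export
first_straight_angle <- function(traj, max_dev_deg = 10) {
  n <- length(traj$t)
  if (n < 2)
    stop_named("degenerate_angle", "trial %s: < 2 samples", traj$trial_id)
  hx <- diff(traj$x); hy <- diff(traj$y)
  if (hx[1] == 0 && hy[1] == 0)
    stop_named("degenerate_angle",
               "trial %s: zero displacement over first segment", traj$trial_id)
  head_deg <- (rad2deg(atan2(hy, hx))) %% 360
  end <- 2L
  for (i in seq_len(n - 1)[-1]) {
    if ((hx[i] == 0 && hy[i] == 0) ||
        ang_diff(head_deg[i], head_deg[i - 1]) > max_dev_deg) break
    end <- i + 1L
  }
  theta <- branch_angle(traj$x[1], traj$y[1], traj$x[end], traj$y[end])
  list(theta = theta, axial = axial_fold(theta), end_index = end,
       length = arc_length(traj_points(traj)[seq_len(end), , drop = FALSE]))
}

#' Start-to-end angle of a trajectory
#'
#' The two-branch arccos formula applied to the first sample (first point
#' out of the chamber) and the last sample (last point before turn-back).
#'
#' @param traj A `fish_trajectory` cropped at turn-back.
#' @return List with `theta` (degrees in \[0, 360)) and `axial`.
#' @export
angle_start_end <- function(traj) {
  n <- length(traj$t)
  if (n < 2)
    stop_named("degenerate_angle", "trial %s: < 2 samples", traj$trial_id)
  theta <- branch_angle(traj$x[1], traj$y[1], traj$x[n], traj$y[n])
  list(theta = theta, axial = axial_fold(theta))
}

#' Axial circular mean
#'
#' Angles are doubled onto the full circle, the vector-mean direction taken,
#' and the result halved back to \[0, 180).
#'
#' @param angles Axial angles in degrees.
#' @return Mean axial direction in degrees, or `NA` with a warning when the
#'   doubled resultant vanishes (perfectly balanced sample).
#' @export
circular_mean_axial <- function(angles) {
  if (!length(angles))
    stop_named("contract_error", "empty angular sample")
  th <- deg2rad(2 * (angles %% 180))
  S <- mean(sin(th)); C <- mean(cos(th))
  if (sqrt(S^2 + C^2) < 1e-12) {
    warning("axial mean undefined: zero resultant")
    return(NA_real_)
  }
  (rad2deg(atan2(S, C)) / 2) %% 180
}

#' Rayleigh test of uniformity for axial data
#'
#' Computed on the doubled angles; p-value from the standard
#' Greenwood-Durand series approximation.
#'
#' @param angles Axial angles in degrees, n >= 3.
#' @return List with `r_bar` (mean resultant length of the doubled sample,
#'   in \[0, 1\]), `statistic` (Z = n R^2) and `p`.
#' @export
rayleigh_test_axial <- function(angles) {
  n <- length(angles)
  if (n < 3)
    stop_named("insufficient_sample", "Rayleigh test needs n >= 3")
  th <- deg2rad(2 * (angles %% 180))
  R <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(r_bar = R, statistic = Z, p = min(1, max(0, p)))
}

# --- von Mises machinery (doubled-angle scale, radians) ------------------

log_i0 <- function(kappa) {
  kappa <- pmin(pmax(kappa, 0), 700)   # guard optimizer excursions
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

dvm_log <- function(theta, mu, kappa) {
  kappa * cos(theta - mu) - log(2 * pi) - log_i0(kappa)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, >= 0.
#' @return Angles in radians in \[0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop_named("contract_error", "kappa must be >= 0")
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# Fisher's approximation to the inverse of A(kappa) = I1/I0, for closed-form
# unimodal starts and as an independent cross-check of the optimiser.
a1inv <- function(R) {
  if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
}

# Model family (directions on the doubled circle). Mixture density:
# lambda * vM(mu1, k1) + (1 - lambda) * second component.
vm_family <- function() {
  list(
    M1  = list(npar = 0, desc = "uniform"),
    M2A = list(npar = 2, desc = "unimodal"),
    M2B = list(npar = 2, desc = "axial bimodal, equal weights"),
    M2C = list(npar = 3, desc = "axial bimodal, free weight"),
    M3A = list(npar = 3, desc = "unimodal + uniform"),
    M3B = list(npar = 3, desc = "axial bimodal + uniform"),
    M4A = list(npar = 3, desc = "bimodal, shared kappa, equal weights"),
    M4B = list(npar = 4, desc = "bimodal, shared kappa, free weight"),
    M5A = list(npar = 4, desc = "homogeneous bimodal (free modes/kappas, equal weights)"),
    M5B = list(npar = 5, desc = "bimodal (free modes/kappas/weight)")
  )
}

# full parameter vector (mu1, mu2, k1, k2, lambda) from a model's free
# parameters
vm_expand <- function(model, p) {
  switch(model,
    M1  = c(0, 0, 0, 0, 1),
    M2A = c(p[1], 0, p[2], 0, 1),
    M2B = c(p[1], p[1] + pi, p[2], p[2], 0.5),
    M2C = c(p[1], p[1] + pi, p[2], p[2], p[3]),
    M3A = c(p[1], 0, p[2], 0, p[3]),          # second component uniform
    M3B = c(p[1], p[1] + pi, p[2], p[2], p[3]),
    M4A = c(p[1], p[2], p[3], p[3], 0.5),
    M4B = c(p[1], p[2], p[3], p[3], p[4]),
    M5A = c(p[1], p[2], p[3], p[4], 0.5),
    M5B = c(p[1], p[2], p[3], p[4], p[5]))
}

vm_loglik <- function(model, p, theta) {
  q <- vm_expand(model, p)
  mu1 <- q[1]; mu2 <- q[2]; k1 <- q[3]; k2 <- q[4]; lam <- q[5]
  if (model == "M1") return(-length(theta) * log(2 * pi))
  c1 <- exp(dvm_log(theta, mu1, k1))
  c2 <- if (model == "M3A") rep(1 / (2 * pi), length(theta))
        else if (model == "M3B")
          0.5 * exp(dvm_log(theta, mu1, k1)) + 0.5 * exp(dvm_log(theta, mu2, k2))
        else exp(dvm_log(theta, mu2, k2))
  if (model == "M3B") {
    dens <- lam * c2 + (1 - lam) / (2 * pi)
  } else {
    dens <- lam * c1 + (1 - lam) * c2
  }
  sum(log(pmax(dens, 1e-300)))
}

# Bounds guard the two known pathologies of mixture MLE: the likelihood is
# unbounded as a component's concentration diverges on a chance cluster, so
# kappa is capped at 227.6 (mean resultant length ~0.999) and free mixing
# weights are floored at 0.1 (a mode carrying < 10% of trials is not
# evidence of orientation).
vm_kappa_max <- 227.583
vm_lambda_rng <- c(0.1, 0.9)

vm_bounds <- function(model) {
  lo_mu <- -2 * pi; hi_mu <- 4 * pi
  km <- vm_kappa_max; ll <- vm_lambda_rng[1]; lh <- vm_lambda_rng[2]
  switch(model,
    M2A = list(lo = c(lo_mu, 0), hi = c(hi_mu, km)),
    M2B = list(lo = c(lo_mu, 0), hi = c(hi_mu, km)),
    M2C = list(lo = c(lo_mu, 0, ll), hi = c(hi_mu, km, lh)),
    M3A = list(lo = c(lo_mu, 0, ll), hi = c(hi_mu, km, lh)),
    M3B = list(lo = c(lo_mu, 0, ll), hi = c(hi_mu, km, lh)),
    M4A = list(lo = c(lo_mu, lo_mu, 0), hi = c(hi_mu, hi_mu, km)),
    M4B = list(lo = c(lo_mu, lo_mu, 0, ll), hi = c(hi_mu, hi_mu, km, lh)),
    M5A = list(lo = c(lo_mu, lo_mu, 0, 0), hi = c(hi_mu, hi_mu, km, km)),
    M5B = list(lo = c(lo_mu, lo_mu, 0, 0, ll),
               hi = c(hi_mu, hi_mu, km, km, lh)))
}

vm_starts <- function(model, theta, n_starts) {
  # deterministic start from the sample moments plus random restarts
  S <- mean(sin(theta)); C <- mean(cos(theta))
  mu_hat <- atan2(S, C) %% (2 * pi)
  k_hat <- max(0.1, a1inv(min(0.999, sqrt(S^2 + C^2))))
  base <- switch(model,
    M2A = c(mu_hat, k_hat), M2B = c(mu_hat, k_hat),
    M2C = c(mu_hat, k_hat, 0.5), M3A = c(mu_hat, k_hat, 0.7),
    M3B = c(mu_hat, k_hat, 0.7), M4A = c(mu_hat, mu_hat + pi / 2, k_hat),
    M4B = c(mu_hat, mu_hat + pi / 2, k_hat, 0.5),
    M5A = c(mu_hat, mu_hat + pi / 2, k_hat, k_hat),
    M5B = c(mu_hat, mu_hat + pi / 2, k_hat, k_hat, 0.5))
  starts <- list(base)
  bb <- vm_bounds(model)
  for (i in seq_len(max(0, n_starts - 1))) {
    p <- base
    nmu <- sum(grepl("mu", vm_par_names(model)))
    p[seq_len(nmu)] <- stats::runif(nmu, 0, 2 * pi)
    kidx <- grep("kappa", vm_par_names(model))
    p[kidx] <- stats::runif(length(kidx), 0.2, 20)
    starts[[i + 1]] <- pmin(pmax(p, bb$lo + 1e-6), bb$hi - 1e-6)
  }
  starts
}

vm_par_names <- function(model) {
  switch(model,
    M2A = c("mu1", "kappa1"), M2B = c("mu1", "kappa1"),
    M2C = c("mu1", "kappa1", "lambda"),
    M3A = c("mu1", "kappa1", "lambda"), M3B = c("mu1", "kappa1", "lambda"),
    M4A = c("mu1", "mu2", "kappa1"),
    M4B = c("mu1", "mu2", "kappa1", "lambda"),
    M5A = c("mu1", "mu2", "kappa1", "kappa2"),
    M5B = c("mu1", "mu2", "kappa1", "kappa2", "lambda"))
}

fit_one_vm <- function(model, theta, n_starts = 10) {
  if (model == "M1") {
    ll <- -length(theta) * log(2 * pi)
    return(list(model = model, par = numeric(0), loglik = ll,
                converged = TRUE))
  }
  bb <- vm_bounds(model)
  best <- NULL
  for (p0 in vm_starts(model, theta, n_starts)) {
    fit <- tryCatch(
      stats::optim(p0, function(p) -vm_loglik(model, p, theta),
                   method = "L-BFGS-B", lower = bb$lo, upper = bb$hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(model = model, par = NULL, loglik = NA_real_,
                converged = FALSE))
  list(model = model, par = best$par, loglik = -best$value,
       converged = TRUE)
}

#' Fit the von Mises mixture model family to axial angles
#'
#' Angles are doubled onto the full circle and the ten-model nested family
#' of uniform / unimodal / bimodal von Mises mixtures (M1, M2A..M5B) is fit
#' by maximum likelihood, each model from multiple restarts of a bounded
#' quasi-Newton optimiser. Models are ranked by AIC; the likelihood-ratio
#' statistic of the best model against the uniform M1 is reported.
#'
#' Family (on the doubled circle; lambda is the first-component weight):
#' M1 uniform; M2A unimodal; M2B axial bimodal (mu2 = mu1 + 180, shared
#' kappa, equal weights); M2C as M2B with free weight; M3A unimodal +
#' uniform; M3B axial bimodal + uniform; M4A bimodal with free second mode,
#' shared kappa, equal weights; M4B as M4A with free weight; M5A
#' homogeneous bimodal (free modes and kappas, equal weights); M5B fully
#' free bimodal.
#'
#' Model selection uses the parsimony convention: among all models within
#' `aic_window` AIC units of the minimum (default 2, the usual
#' equivalence band), the one with fewest parameters is selected. This
#' guards against the ~tens-of-percent rate at which a richer nested model
#' beats the true one by chance under a strict AIC argmin.
#'
#' @param angles Axial angles in degrees, n >= 5.
#' @param n_starts Random restarts per model (>= 10 recommended).
#' @param seed Optional seed for the restarts.
#' @param aic_window AIC-equivalence band for the parsimony selection.
#' @return An object of class `circ_family_fit`: a list with `table` (one
#'   row per converged model: model, n_params, loglik, AIC, delta_AIC,
#'   mu1/mu2 on the axial scale in degrees, kappa1/kappa2, lambda),
#'   `best` (selected model id), and `lr_vs_uniform` (statistic, df, p).
#' @export
fit_circular_model_family <- function(angles, n_starts = 10, seed = NULL,
                                      aic_window = 2) {
  if (length(angles) < 5)
    stop_named("insufficient_sample", "model family fit needs n >= 5")
  theta <- deg2rad(2 * (angles %% 180)) %% (2 * pi)
  fam <- vm_family()
  fits <- with_seed(seed, lapply(names(fam), function(m)
    fit_one_vm(m, theta, n_starts)))
  names(fits) <- names(fam)
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!ok))
    warning("non-converged fits excluded: ",
            paste(names(fits)[!ok], collapse = ", "))
  fits <- fits[ok]
  rows <- lapply(fits, function(f) {
    q <- if (f$model == "M1") c(NA, NA, NA, NA, 1) else vm_expand(f$model, f$par)
    npar <- fam[[f$model]]$npar
    data.frame(model = f$model, n_params = npar, loglik = f$loglik,
               AIC = 2 * npar - 2 * f$loglik,
               mu1_axial_deg = if (is.na(q[1])) NA else (rad2deg(q[1] %% (2 * pi)) / 2) %% 180,
               mu2_axial_deg = if (is.na(q[2]) || f$model == "M3A") NA
                               else (rad2deg(q[2] %% (2 * pi)) / 2) %% 180,
               kappa1 = q[3], kappa2 = if (f$model == "M3A") NA else q[4],
               lambda = q[5], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  # parsimony selection: among models within `aic_window` AIC units of the
  # minimum, pick the one with fewest parameters (ties -> lower AIC); the
  # AIC-minimal model always has delta_AIC = 0 in the table
  cand <- tab[tab$delta_AIC <= aic_window, ]
  best <- cand$model[order(cand$n_params, cand$AIC)][1]
  bi <- match(best, tab$model)
  ll1 <- fits[["M1"]]$loglik
  lr <- 2 * (tab$loglik[bi] - ll1)
  df <- tab$n_params[bi]
  lr_p <- if (df > 0) stats::pchisq(max(lr, 0), df, lower.tail = FALSE) else 1
  structure(list(table = tab, best = best,
                 lr_vs_uniform = list(statistic = lr, df = df, p = lr_p)),
            class = "circ_family_fit")
}

#' Modality class of a model id
#'
#' @param model Model id from the family (M1 .. M5B).
#' @return `"uniform"`, `"unimodal"` or `"bimodal"`.
#' @export
circ_model_class <- function(model) {
  vapply(model, function(m) switch(m, M1 = "uniform",
                                   M2A = , M3A = "unimodal", "bimodal"),
         character(1), USE.NAMES = FALSE)
}

#' @export
print.circ_family_fit <- function(x, ...) {
  cat(sprintf("<circ_family_fit: best %s, LR vs uniform %.2f (p = %.3g)>\n",
              x$best, x$lr_vs_uniform$statistic, x$lr_vs_uniform$p))
  print(x$table[, c("model", "n_params", "loglik", "AIC", "delta_AIC")],
        digits = 4)
  invisible(x)
}
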