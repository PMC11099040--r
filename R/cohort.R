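#' One-sample bootstrap t test
#'
#' The observed t statistic of the sample against `mu0` is compared with a
#' null distribution obtained by resampling, with replacement, the sample
#' recentred to `mu0`. The two-sided p-value uses the +1-corrected
#' estimator `(1 + #{|t*| >= |t|}) / (reps + 1)`. The bootstrapped mean and
#' percentile 95% CI come from resampling the original (uncentred) sample.
#'
#' @param sample Numeric vector, n >= 3.
#' @param mu0 Null expectation.
#' @param reps Bootstrap replicates (default 9999).
#' @param seed Optional seed.
#' @return A list (class `homing_test`) with `statistic_name = "t"`,
#'   `statistic`, `df`, `p`, `mean`, `ci95`, `n_boot`.
#' @export
bootstrap_t_test <- function(sample, mu0, reps = 9999, seed = NULL) {
  n <- length(sample)
  if (n < 3) stop_named("insufficient_sample", "bootstrap t needs n >= 3")
  s <- stats::sd(sample)
  if (s == 0) {
    p <- if (mean(sample) == mu0) 1 else 2 / (reps + 1)
    return(structure(list(statistic_name = "t",
                          statistic = if (mean(sample) == mu0) 0 else Inf,
                          df = n - 1, p = p, mean = mean(sample),
                          ci95 = c(mean(sample), mean(sample)),
                          n_boot = reps), class = "homing_test"))
  }
  t_obs <- (mean(sample) - mu0) / (s / sqrt(n))
  centred <- sample - mean(sample) + mu0
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
    bm <- matrix(centred[idx], nrow = reps)
    mstar <- rowMeans(bm)
    sstar <- sqrt(rowSums((bm - mstar)^2) / (n - 1))
    tstar <- (mstar - mu0) / (sstar / sqrt(n))
    tstar[!is.finite(tstar)] <- Inf * sign(mstar[!is.finite(tstar)] - mu0)
    p <- (1 + sum(abs(tstar) >= abs(t_obs))) / (reps + 1)
    om <- matrix(sample[idx], nrow = reps)
    boot_means <- rowMeans(om)
    ci <- unname(stats::quantile(boot_means, c(0.025, 0.975)))
    structure(list(statistic_name = "t", statistic = t_obs, df = n - 1,
                   p = p, mean = mean(boot_means), ci95 = ci, n_boot = reps),
              class = "homing_test")
  })
}

#' One-sample Wilcoxon signed-rank test
#'
#' V statistic and two-sided p-value (exact for n <= 25 without ties, else
#' normal approximation with continuity correction, via
#' [stats::wilcox.test()]); zero differences are dropped.
#'
#' @param sample Numeric vector, n >= 3.
#' @param mu0 Null location.
#' @return A `homing_test` list with `statistic_name = "V"`.
#' @export
wilcoxon_signed_rank <- function(sample, mu0) {
  if (length(sample) < 3)
    stop_named("insufficient_sample", "Wilcoxon test needs n >= 3")
  d <- sample - mu0
  if (all(d == 0)) {
    warning("all differences zero; p = 1")
    return(structure(list(statistic_name = "V", statistic = 0,
                          df = NA_integer_, p = 1, mean = mean(sample),
                          ci95 = c(NA_real_, NA_real_), n_boot = NA_integer_),
                     class = "homing_test"))
  }
  wt <- suppressWarnings(stats::wilcox.test(sample, mu = mu0))
  structure(list(statistic_name = "V", statistic = unname(wt$statistic),
                 df = NA_integer_, p = wt$p.value, mean = mean(sample),
                 ci95 = c(NA_real_, NA_real_), n_boot = NA_integer_),
            class = "homing_test")
}

#' Shapiro-Wilk normality check
#'
#' Gates the location test downstream: bootstrap t when p > 0.05, Wilcoxon
#' otherwise.
#'
#' @param sample Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A `homing_test` list with `statistic_name = "W"`.
#' @export
normality_check <- function(sample) {
  n <- length(sample)
  if (n < 3 || n > 5000)
    stop_named("contract_error", "Shapiro test needs 3 <= n <= 5000")
  if (stats::sd(sample) == 0)
    stop_named("contract_error", "constant sample has no defined normality")
  st <- stats::shapiro.test(sample)
  structure(list(statistic_name = "W", statistic = unname(st$statistic),
                 df = NA_integer_, p = st$p.value, mean = mean(sample),
                 ci95 = c(NA_real_, NA_real_), n_boot = NA_integer_),
            class = "homing_test")
}

#' Normality-gated one-sample location test
#'
#' Applies the practice used for the group-versus-expectation comparisons:
#' Shapiro-Wilk first, then a bootstrap t test when normality is not
#' rejected (p > 0.05) and a Wilcoxon signed-rank test otherwise.
#'
#' @inheritParams bootstrap_t_test
#' @return A `homing_test` list, with an added `shapiro_p` field.
#' @export
location_test_vs_expectation <- function(sample, mu0, reps = 9999,
                                         seed = NULL) {
  sh <- normality_check(sample)
  res <- if (sh$p > 0.05) bootstrap_t_test(sample, mu0, reps, seed)
         else wilcoxon_signed_rank(sample, mu0)
  res$shapiro_p <- sh$p
  res
}

#' @export
print.homing_test <- function(x, ...) {
  cat(sprintf("<%s = %.3f, p = %.4g, mean = %.2f [%.2f; %.2f]>\n",
              x$statistic_name, x$statistic, x$p, x$mean,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Kruskal-Wallis comparison of travel distance across strategy groups
#'
#' H statistic (reported as chi-squared with df = groups - 1) plus a
#' post-hoc table of pairwise two-sample Wilcoxon tests with Holm-Bonferroni
#' adjustment. Groups with fewer than `min_n` observations are dropped with
#' a warning.
#'
#' @param values Numeric vector (e.g. full-path lengths, cm).
#' @param groups Factor or character vector of group labels (commonly the
#'   strategy label with APC split by displacement, giving five groups).
#' @param min_n Minimum group size retained.
#' @return List with `statistic` (H), `df`, `p` and `posthoc` (matrix of
#'   Holm-adjusted pairwise p-values).
#' @export
distance_across_groups <- function(values, groups, min_n = 2) {
  groups <- as.character(groups)
  tab <- table(groups)
  drop <- names(tab)[tab < min_n]
  if (length(drop)) {
    warning("dropping groups with < ", min_n, " observations: ",
            paste(drop, collapse = ", "))
    keep <- !groups %in% drop
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop_named("contract_error", "need >= 2 groups")
  if (length(unique(values)) == 1) {
    # all observations tied: no rank variation, H is 0 by convention
    k <- length(unique(groups))
    ph <- matrix(1, k - 1, k - 1,
                 dimnames = list(sort(unique(groups))[-1],
                                 sort(unique(groups))[-k]))
    return(list(statistic = 0, df = k - 1, p = 1, posthoc = ph))
  }
  kw <- stats::kruskal.test(values, factor(groups))
  ph <- suppressWarnings(
    stats::pairwise.wilcox.test(values, factor(groups), p.adjust.method = "holm"))
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, posthoc = ph$p.value)
}

# per-observation score contributions of a fitted multinomial logit
multinom_scores <- function(fit, X, y_mat) {
  P <- fit$fitted.values
  if (is.null(dim(P))) P <- cbind(1 - P, P)
  else if (ncol(P) == 1) P <- cbind(1 - P[, 1], P[, 1])
  K <- ncol(P)
  # coefficients are for classes 2..K vs reference; score for class k,
  # covariate j: (1[y = k] - p_k) * x_j
  do.call(cbind, lapply(2:K, function(k) (y_mat[, k] - P[, k]) * X))
}

#' Multinomial strategy-choice model with cluster-robust errors
#'
#' Fits the log-odds of following each model strategy (PI, APC, RR) versus
#' RANDOM as a function of fish age, swimming speed, displacement and trial
#' number, with per-fish dependence handled by cluster-robust (sandwich)
#' standard errors: each fish contributes at most two trials, so a
#' fish-level variance component is not identifiable and clustered errors
#' are used instead of a random intercept.
#'
#' @param records Data frame with columns `fish_id`, `age`, `swim_speed`,
#'   `displacement`, `trial_number`, `label`.
#' @return List with `coefficients` (data.frame: outcome, term, estimate,
#'   robust SE, z, p), `fit` (the underlying [nnet::multinom] object) and
#'   `vcov_cluster`.
#' @export
strategy_choice_model <- function(records) {
  need <- c("fish_id", "age", "swim_speed", "displacement", "trial_number",
            "label")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_named("contract_error", "records missing columns: %s",
               paste(miss, collapse = ", "))
  labs <- unique(records$label)
  if (length(labs) < 2)
    stop_named("contract_error", "need >= 2 strategies present")
  for (v in c("age", "swim_speed"))
    if (stats::sd(records[[v]]) == 0)
      stop_named("contract_error", "covariate %s is constant", v)
  records$label <- stats::relevel(factor(records$label),
                                  ref = if ("RANDOM" %in% labs) "RANDOM"
                                        else sort(labs)[1])
  records$displacement <- factor(records$displacement)
  fit <- nnet::multinom(
    label ~ age + swim_speed + displacement + trial_number,
    data = records, trace = FALSE, maxit = 500)
  X <- stats::model.matrix(~ age + swim_speed + displacement + trial_number,
                           data = records)
  y_mat <- stats::model.matrix(~ 0 + label, data = records)
  colnames(y_mat) <- levels(records$label)
  y_mat <- y_mat[, c(levels(records$label)), drop = FALSE]
  U <- multinom_scores(fit, X, y_mat)
  # cluster (fish) sums of scores -> meat; bread from the model's vcov
  G <- rowsum(U, records$fish_id)
  meat <- crossprod(as.matrix(G))
  ng <- nrow(G)
  bread <- stats::vcov(fit)
  Vc <- bread %*% meat %*% bread * ng / (ng - 1)
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(levels(records$label)[2],
                                                     names(co)))
  est <- as.vector(t(co))
  terms <- rep(colnames(co), times = nrow(co))
  outs <- rep(rownames(co), each = ncol(co))
  # nnet's vcov orders parameters outcome-major, term-minor (same as t(co))
  se <- sqrt(pmax(diag(Vc), 0))
  z <- est / se
  coefs <- data.frame(outcome = outs, term = terms, estimate = est,
                      se_cluster = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  list(coefficients = coefs, fit = fit, vcov_cluster = Vc)
}

#' Visual acuity from lens diameter
#'
#' Published regression for ray-finned fishes with lens diameter below
#' 10 mm: acuity (cycles per degree) = 2.2957 + 1.225 x lens diameter (mm).
#'
#' @param lens_diameter_mm Lens diameter in mm, in (0, 10).
#' @return Estimated visual acuity in cycles per degree.
#' @examples
#' visual_acuity_cpd(1)  # 3.5207
#' @export
visual_acuity_cpd <- function(lens_diameter_mm) {
  if (any(lens_diameter_mm <= 0))
    stop_named("contract_error", "lens diameter must be positive")
  if (any(lens_diameter_mm >= 10))
    stop_named("out_of_calibration",
               "regression calibrated for lens diameter < 10 mm")
  2.2957 + 1.225 * lens_diameter_mm
}
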