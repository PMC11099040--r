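#' Run the full homing-strategy analysis pipeline
#'
#' Executes, in order: turn-back cropping, per-trial classification against
#' the three model trajectories with the random-trajectory null, orientation
#' angle extraction, circular model-family fits on the first and
#' start-to-end angles, group-level tests of angles and full-path distances
#' against the model expectations (Shapiro-gated bootstrap t / Wilcoxon),
#' the across-group distance test, and the covariate strategy-choice model.
#' A trial that fails validation or cropping is flagged and excluded; the
#' remaining trials are processed.
#'
#' @param trajectories Named list of `fish_trajectory` objects (e.g. from
#'   [read_trajectories()] or [simulate_cohort()]).
#' @param metadata Data frame with columns `trial_id`, `fish_id`, `age`,
#'   `swim_speed`, `displacement`, `trial_number`.
#' @param config An [arena_config()].
#' @param rule Null-threshold rule passed to [classify_trial()].
#' @param n_null Random trajectories per null (default 10000).
#' @param boot_reps Bootstrap replicates for the group tests.
#' @param seed Integer seed; every stochastic stage derives its own
#'   sub-stream from it, so a run is reproducible end to end.
#' @param out_dir Optional directory for CSV outputs (classification,
#'   angles, group stats, circular fits) plus a JSON manifest.
#' @return An object of class `homing_pipeline`: list with
#'   `classification` (data.frame), `angles` (data.frame), `group_stats`
#'   (data.frame), `circ_fits` (list for first and start-end angles),
#'   `distance_test`, `choice_model`, `failed` (data.frame of skipped
#'   trials) and `manifest`.
#' @export
run_pipeline <- function(trajectories, metadata, config = arena_config(),
                         rule = c("sd_uniform", "sd_normal", "q20"),
                         n_null = 10000, boot_reps = 9999, seed = 1,
                         out_dir = NULL) {
  rule <- match.arg(rule)
  if (!length(trajectories))
    stop_named("contract_error", "no trajectories supplied")
  meta_idx <- match(names(trajectories), metadata$trial_id)
  if (any(is.na(meta_idx)))
    stop_named("validation_error", "metadata missing trials: %s",
               paste(names(trajectories)[is.na(meta_idx)], collapse = ", "))
  metadata <- metadata[meta_idx, ]

  models_by_disp <- lapply(
    stats::setNames(c("lateral", "diagonal"), c("lateral", "diagonal")),
    function(d) stats::setNames(
      lapply(c("PI", "APC", "RR"), function(s)
        build_model_trajectory(config, s, d)), c("PI", "APC", "RR")))

  cls_rows <- list(); ang_rows <- list(); failed <- list()
  for (i in seq_along(trajectories)) {
    tid <- names(trajectories)[i]
    res <- tryCatch({
      tr <- trajectories[[i]]
      disp <- metadata$displacement[i]
      door <- displaced_chamber_position(config, disp)
      cr <- crop_at_turnback(tr, door,
                             cone_deg = config$turnback_cone_deg,
                             persistence = config$turnback_persistence,
                             analysis_window = config$analysis_window)
      cropped <- cr$trajectory
      models <- models_by_disp[[disp]]
      nul <- build_null(cropped, models$PI, n = n_null,
                        seed = child_seed(seed, i))
      cl <- classify_trial(cropped, models, nul, rule = rule, trial_id = tid)
      fa <- first_straight_angle(cropped)
      se <- angle_start_end(cropped)
      full_len <- arc_length(traj_points(cropped))
      list(
        cls = data.frame(
          trial_id = tid, fish_id = tr$fish_id, displacement = disp,
          d_PI = cl$mean_distance_to[["PI"]],
          d_APC = cl$mean_distance_to[["APC"]],
          d_RR = cl$mean_distance_to[["RR"]],
          best_strategy = cl$best_strategy, best_distance = cl$best_distance,
          null_mu = nul$mu, null_sd_uniform = nul$sd_uniform,
          null_sd_normal = nul$sd_normal, null_q20 = nul$q20,
          threshold = cl$threshold, rule = rule, label = cl$label,
          crop_index = cr$crop_index, full_length_cm = full_len,
          stringsAsFactors = FALSE),
        ang = data.frame(
          trial_id = tid, first_angle_deg = fa$theta,
          first_angle_axial = fa$axial, start_end_angle_deg = se$theta,
          start_end_axial = se$axial, stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(res, "condition")) {
      failed[[tid]] <- data.frame(trial_id = tid,
                                  reason = conditionMessage(res),
                                  stringsAsFactors = FALSE)
    } else {
      cls_rows[[tid]] <- res$cls
      ang_rows[[tid]] <- res$ang
    }
  }
  if (!length(cls_rows))
    stop_named("no_analysable_trials", "no analysable trials")
  classification <- do.call(rbind, cls_rows)
  angles <- do.call(rbind, ang_rows)
  rownames(classification) <- rownames(angles) <- NULL

  circ_fits <- list(first = NULL, start_end = NULL)
  if (nrow(angles) >= 5) {
    circ_fits$first <- fit_circular_model_family(
      angles$first_angle_axial, seed = child_seed(seed, 90001))
    circ_fits$start_end <- fit_circular_model_family(
      angles$start_end_axial, seed = child_seed(seed, 90002))
  }

  merged <- merge(classification, angles, by = "trial_id")
  group_stats <- group_expectation_tests(merged, boot_reps = boot_reps,
                                         seed = child_seed(seed, 90003))

  # across-group distance test on the full (pre-turn-back) path lengths,
  # APC split by displacement (five groups when all labels occur)
  grp <- ifelse(merged$label == "APC",
                paste0("APC_", merged$displacement), merged$label)
  distance_test <- tryCatch(
    suppressWarnings(distance_across_groups(merged$full_length_cm, grp)),
    homingtraj_error = function(e) NULL)

  choice_model <- tryCatch({
    recs <- merge(merged[, c("trial_id", "label")],
                  metadata, by = "trial_id")
    strategy_choice_model(recs)
  }, error = function(e) NULL)

  manifest <- list(
    package_version = as.character(utils::packageVersion("homingtraj")),
    seed = seed, rule = rule, n_null = n_null, boot_reps = boot_reps,
    cone_deg = config$turnback_cone_deg,
    persistence = config$turnback_persistence,
    analysis_window = config$analysis_window,
    n_trials_in = length(trajectories),
    n_trials_analysed = nrow(classification),
    config = unclass(config))

  out <- structure(list(classification = classification, angles = angles,
                        group_stats = group_stats, circ_fits = circ_fits,
                        distance_test = distance_test,
                        choice_model = choice_model,
                        failed = if (length(failed))
                          do.call(rbind, failed) else NULL,
                        manifest = manifest),
                   class = "homing_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# Table-2-shaped tests: per strategy group (APC split by displacement),
# first angle, start-end angle and full travelled distance against the
# printed model expectations, each via the Shapiro-gated chooser. Groups
# with n < 3 report raw values only.
group_expectation_tests <- function(merged, boot_reps = 9999, seed = NULL) {
  exps <- strategy_expectations()
  rows <- list()
  groups <- list(
    PI = merged$label == "PI",
    APC_lateral = merged$label == "APC" & merged$displacement == "lateral",
    APC_diagonal = merged$label == "APC" & merged$displacement == "diagonal",
    RR = merged$label == "RR")
  specs <- list(
    c(metric = "first_angle", col = "first_angle_axial",
      exp_col = "expected_first_angle_deg"),
    c(metric = "start_end_angle", col = "start_end_axial",
      exp_col = "expected_start_end_angle_deg"),
    c(metric = "distance", col = "full_length_cm",
      exp_col = "expected_length_cm"))
  k <- 0
  for (g in names(groups)) {
    sel <- groups[[g]]
    strat <- sub("_.*", "", g)
    disp <- if (grepl("_", g)) sub(".*_", "", g) else "lateral"
    for (spc in specs) {
      k <- k + 1
      e <- exps[exps$strategy == strat & exps$displacement == disp,
                spc[["exp_col"]]]
      vals <- merged[sel, spc[["col"]]]
      n <- length(vals)
      if (n < 3 || stats::sd(vals) == 0) {
        rows[[k]] <- data.frame(
          group = g, metric = spc[["metric"]], n = n, test = "none",
          statistic = NA_real_, p = NA_real_,
          mean = if (n) mean(vals) else NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, expectation = e,
          values = paste(round(vals, 2), collapse = ";"),
          stringsAsFactors = FALSE)
        next
      }
      tt <- location_test_vs_expectation(vals, e, reps = boot_reps,
                                         seed = child_seed(seed, k))
      rows[[k]] <- data.frame(
        group = g, metric = spc[["metric"]], n = n,
        test = if (tt$statistic_name == "t") "bootstrap_t" else "wilcoxon",
        statistic = tt$statistic, p = tt$p, mean = tt$mean,
        ci_lo = tt$ci95[1], ci_hi = tt$ci95[2], expectation = e,
        values = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$classification,
                   file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  utils::write.csv(res$angles, file.path(out_dir, "angles.csv"),
                   row.names = FALSE)
  utils::write.csv(res$group_stats, file.path(out_dir, "group_stats.csv"),
                   row.names = FALSE)
  for (nm in names(res$circ_fits)) {
    if (!is.null(res$circ_fits[[nm]]))
      utils::write.csv(res$circ_fits[[nm]]$table,
                       file.path(out_dir, paste0("circ_fit_", nm, ".csv")),
                       row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(res$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    utils::write.csv(
      data.frame(key = names(unlist(res$manifest)),
                 value = as.character(unlist(res$manifest))),
      file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Strategy label counts
#'
#' @param x A `homing_pipeline` result or classification data.frame.
#' @return Named integer vector of counts over PI, APC, RR, RANDOM.
#' @export
strategy_counts <- function(x) {
  cls <- if (inherits(x, "homing_pipeline")) x$classification else x
  tab <- table(factor(cls$label, levels = c("PI", "APC", "RR", "RANDOM")))
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.homing_pipeline <- function(x, ...) {
  cnt <- strategy_counts(x)
  cat(sprintf("<homing_pipeline: %d trials analysed (%s)>\n",
              nrow(x$classification),
              paste(names(cnt), cnt, sep = "=", collapse = ", ")))
  if (!is.null(x$failed))
    cat(sprintf("  %d trial(s) failed validation\n", nrow(x$failed)))
  invisible(x)
}
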