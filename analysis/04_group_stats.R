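#!/usr/bin/env Rscript
# Step 4: group-level tests against the model expectations.
#
# For each labelled group (APC split by displacement) the first angle,
# start-end angle and full pre-turn-back distance are tested against the
# printed expectations (PI 45 deg / 38.6 cm; APC lateral 135 deg / 38.6 cm;
# APC diagonal 180 deg / 27.3 cm; RR 90 deg first, 45 deg start-end,
# 54.5 cm), with a Shapiro gate choosing bootstrap t (9999 reps) or
# Wilcoxon. Also the across-group Kruskal-Wallis on distance with a
# Holm-adjusted pairwise Wilcoxon posthoc.

suppressMessages(library(homingtraj))

gs <- read.csv("results/group_stats.csv", stringsAsFactors = FALSE)
if (!nrow(gs)) stop("run analysis/02_classify.R first")
print(gs[, c("group", "metric", "n", "test", "statistic", "p", "mean",
             "ci_lo", "ci_hi", "expectation")], digits = 3)

cls <- read.csv("results/classification.csv", stringsAsFactors = FALSE)
grp <- ifelse(cls$label == "APC", paste0("APC_", cls$displacement),
              cls$label)
dt <- tryCatch(distance_across_groups(cls$full_length_cm, grp),
               error = function(e) NULL)
if (!is.null(dt)) {
  message(sprintf("across-group distance: chi^2 = %.2f, df = %d, p = %.3f",
                  dt$statistic, dt$df, dt$p))
  write.csv(as.data.frame(as.table(dt$posthoc)),
            "results/distance_posthoc.csv", row.names = FALSE)
}
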