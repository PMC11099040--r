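#!/usr/bin/env Rscript
# Step 5: which covariates predict the chosen strategy?
#
# Multinomial logit of the assigned label (PI / APC / RR vs RANDOM) on fish
# age, swim speed, displacement direction and trial number, with per-fish
# cluster-robust standard errors (each fish contributes at most two trials,
# so clustered errors replace a fish-level random intercept).

suppressMessages(library(homingtraj))

cls <- read.csv("results/classification.csv", stringsAsFactors = FALSE)
meta <- read.csv("results/cohort/metadata.csv", stringsAsFactors = FALSE)
recs <- merge(cls[, c("trial_id", "label")], meta, by = "trial_id")

fit <- tryCatch(strategy_choice_model(recs), error = function(e) {
  message("choice model not identifiable on this cohort: ",
          conditionMessage(e))
  NULL
})
if (!is.null(fit)) {
  co <- fit$coefficients
  print(co, digits = 3)
  write.csv(co, "results/strategy_choice_coefficients.csv",
            row.names = FALSE)
  sig <- co[co$term != "(Intercept)" & co$p < 0.05, ]
  if (nrow(sig)) {
    message("covariates with p < 0.05:")
    print(sig[, c("outcome", "term", "estimate", "p")], digits = 3)
  } else {
    message("no covariate reaches p < 0.05 on this cohort")
  }
}
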