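#!/usr/bin/env Rscript
# Temporal-integration analysis: fit logistic (LDF) and exponential (EDF)
# decay laws to each group's mean temporal-order-error curve and pick the
# better law by MSE; then fit the EDF per patient and correlate the
# resulting decay rates with (synthetic) PANSS symptom scores.

suppressPackageStartupMessages(library(blinkstat))
seed <- 20260903
dir.create("results", showWarnings = FALSE)

groups <- list()
for (preset in c("exp1", "exp2")) {
  study <- build_study(preset, seed = seed)
  curves <- aggregate_trials(study$trials)
  for (g in unique(curves$group)) {
    sub <- curves[curves$group == g, ]
    mean_swap <- aggregate(pr_swap ~ lag, data = sub, FUN = mean)
    groups[[g]] <- data.frame(lag = mean_swap$lag,
                              value = mean_swap$pr_swap)
  }
  if (preset == "exp1") exp1_curves <- curves
}

report <- compare_decay_models(groups)
cat("Group-level decay fits (winner by smaller MSE):\n")
print(report, digits = 3)
write.csv(report, "results/decay_model_comparison.csv", row.names = FALSE)

winners <- report[report$winner, c("group", "kind")]
cat("\nWinning law per group:\n"); print(winners, row.names = FALSE)

# per-patient EDF rates and clinical correlation (synthetic PANSS)
pat <- exp1_curves[exp1_curves$group == "patient", ]
rates <- suppressWarnings(subject_decay_rates(pat, kind = "EDF"))
write.csv(rates, "results/patient_decay_rates.csv", row.names = FALSE)
clin <- simulate_clinical_scores(rates, seed = seed)
write.csv(clin, "results/synthetic_panss.csv", row.names = FALSE)

cors <- do.call(rbind, lapply(
  c("panss_positive", "panss_negative", "panss_general", "panss_total"),
  function(v) correlate_decay_with_clinical(rates, clin, v)
))
cat("\nDecay rate vs synthetic PANSS:\n")
print(cors, digits = 3)
write.csv(cors, "results/decay_clinical_correlations.csv",
          row.names = FALSE)
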