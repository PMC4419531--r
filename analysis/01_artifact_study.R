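#!/usr/bin/env Rscript
# Theoretical investigation: does suppression-ratio normalisation create a
# group-by-lag interaction when the only true group difference is a
# baseline shift?
#
# Steps: (1) take the fitted control-group curve (shape 2.1, scale 0.96,
# baseline 0.86, depth 0.87) and refit only the baseline to the same curve
# shifted down by 0.16 -- the patient-group parameterisation; (2) simulate
# 100 subjects per group under that baseline-shift-only null; (3) analyse
# raw and SR-transformed accuracies with the two-way mixed ANOVA, and
# repeat over 200 seeded replicates to estimate rejection rates.

suppressPackageStartupMessages(library(blinkstat))
seed <- 20260901
dir.create("results", showWarnings = FALSE)

control <- gamma_ab_params(2.1, 0.96, 0.86, 0.87, noise_halfwidth = 0.4)

# baseline-only refit: recovers the patient baseline c = 0.70
ctrl0 <- gamma_ab_params(2.1, 0.96, 0.86, 0.87, noise_halfwidth = 0)
shifted <- ab_curve(ctrl0, 1:8)
shifted$value <- shifted$value - 0.16
refit <- fit_gamma_ab(shifted, free = "baseline", init = ctrl0)
cat(sprintf("patient baseline from refit: c = %.4f (control c = 0.86)\n",
            refit$params$baseline))

# one illustrative replicate
st <- run_artifact_study(control, -0.16, 100, 1:8, seed = seed)
cat("\nSingle replicate, raw accuracies:\n"); print(st$anova_raw)
cat("\nSingle replicate, suppression ratios:\n"); print(st$anova_sr)

# Monte-Carlo rejection rates
cat("\nEstimating rejection rates over 200 replicates ...\n")
res <- replicate_artifact_power(control, -0.16, 100, 1:8,
                                n_replicates = 200, seed = seed)
print(res$rates)
write.csv(res$rates, "results/artifact_rejection_rates.csv",
          row.names = FALSE)
write.csv(res$p_values, "results/artifact_replicate_pvalues.csv",
          row.names = FALSE)

raw_int <- subset(res$rates, transform == "raw" & effect == "group:lag")
sr_int <- subset(res$rates, transform == "sr" & effect == "group:lag")
cat(sprintf(paste0(
  "\nRaw-data interaction rejects at %.3f (nominal 0.05); after the SR\n",
  "transform the same null rejects at %.3f -- the normalisation, not the\n",
  "data, produces the interaction.\n"),
  raw_int$rate, sr_int$rate))
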