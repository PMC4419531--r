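# blinkstat

Analysis toolkit for dual-target rapid serial visual presentation (RSVP)
experiments on the attentional blink (AB), built for one methodological
question: when a clinical group (e.g. schizophrenia patients) has a lower
baseline accuracy than controls, does "correcting" for that baseline with
the suppression ratio reveal a true attention deficit — or manufacture
one?

The package provides:

* a generative model of AB accuracy-by-lag curves,
  `v(x) = c − d·Gamma(x; a, b) + e` with uniform per-lag noise
  `e ~ U(−0.4, 0.4)`, plus nonlinear fitting (full, and baseline-only in
  closed form);
* the suppression-ratio transform
  `SR = (Pr(T1) − Pr(T2|T1)) / Pr(T1)` and a Monte-Carlo study showing it
  inflates the group×lag interaction type-I error several-fold under a
  pure baseline-shift null;
* a trial-level synthetic RSVP data generator emulating both study
  designs (TOAs 100–1200 ms with per-group SOA titration; TOAs 50–600 ms
  at a common SOA), with 25% triple-target catch trials and temporal-order
  (swap) errors;
* the analysis stage: aggregation of trials to per-subject curves,
  two-way mixed ANOVA (between: group, within: lag) with simple effects,
  and Bayes factors for the interaction (BIC-based, and a reference
  g-prior implementation with inverse-gamma(0.5, 0.25)/(0.5, 0.5)
  priors);
* logistic vs exponential decay fitting
  (`LDF: b + 1/(1+e^{ax})`, `EDF: b + e^{−ax}`) for swap-rate curves with
  MSE model selection, per-subject decay rates, and clinical score
  correlation;
* pooled-variance t tests recomputed from published summary tables.

## Worked example

Simulate the baseline-shift null — patients differ from controls *only*
by a 0.16 baseline deficit (control curve: shape 2.1, scale 0.96,
baseline 0.86, depth 0.87; patient baseline 0.70, equal blink depth) —
then analyse the same 100+100-subject dataset before and after the
suppression-ratio transform:

```r
library(blinkstat)
control <- gamma_ab_params(2.1, 0.96, 0.86, 0.87)
st <- run_artifact_study(control, baseline_offset = -0.16,
                         n_per_group = 100, lags = 1:8, seed = 20260901)
st$anova_raw
#> Mixed ANOVA (between: group, within: lag)
#>   group      F(1,198) = 174.9, p = 5e-29
#>   lag        F(7,1386) = 52.33, p = 2.053e-66
#>   group:lag  F(7,1386) = 1.83, p = 0.07777
st$anova_sr
#> Mixed ANOVA (between: group, within: lag)
#>   group      F(1,198) = 0.07152, p = 0.7894
#>   lag        F(7,1386) = 43.51, p = 8.77e-56
#>   group:lag  F(7,1386) = 2.537, p = 0.01351
```

On the raw accuracies the analysis tells the truth: a large group effect
(the baseline shift), a large lag effect (the blink), and no interaction
— the groups' blink depths do not differ. After the suppression ratio the
group effect vanishes and a *significant group×lag interaction appears*
(p = 0.014), exactly the signature previous studies read as an
attention deficit. Across 200 replicates the raw interaction rejects at
0.075 (nominal 0.05, inside the exact-binomial 99% band) while the
SR interaction rejects at 0.240:

```r
res <- replicate_artifact_power(control, -0.16, 100, 1:8,
                                n_replicates = 200, seed = 20260901)
subset(res$rates, effect == "group:lag")
#>   transform    effect rejections n_replicates  rate   ci_lower  ci_upper
#> 3       raw group:lag         15          200 0.075 0.03509893 0.1362038
#> 4        sr group:lag         48          200 0.240 0.16674533 0.3260045
```

The numbered scripts under `analysis/` run the full workflow and write
tables under `results/`:

1. `01_artifact_study.R` — baseline-only refit (recovers patient
   c = 0.70) and the Monte-Carlo artifact study above;
2. `02_synthetic_study.R` — synthetic two-group cohorts for both designs,
   baseline-match t tests, mixed ANOVAs for T1, T2|T1 and swap measures,
   interaction Bayes factors;
3. `03_decay_models.R` — group-level LDF/EDF comparison, per-patient EDF
   decay rates, correlation with (synthetic) PANSS scores;
4. `04_summary_tables.R` — published demographic/clinical table t columns
   recomputed from their printed summaries.

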