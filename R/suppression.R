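#' Suppression ratio of conditional T2 accuracy against baseline
#'
#' Normalises `Pr(T2|T1)` by the single-target baseline `Pr(T1)`. The
#' default "deficit" form is
#' \deqn{SR = (Pr(T1) - Pr(T2|T1)) / Pr(T1)}
#' so suppression grows as T2 performance drops, 0 means performance at
#' baseline and 1 means total suppression. `form = "ratio"` gives the plain
#' ratio `Pr(T2|T1) / Pr(T1)` instead; both forms share the nonlinearity
#' that inflates group differences near floor.
#'
#' @param t2_given_t1 numeric vector of conditional T2 accuracies in
#'   `[0, 1]`.
#' @param baseline baseline accuracy `Pr(T1)`, strictly positive; scalar or
#'   vector recycled against `t2_given_t1`.
#' @param form `"deficit"` (default) or `"ratio"`.
#' @return numeric vector of suppression ratios. Values where
#'   `t2_given_t1 > baseline` come out negative under the deficit form;
#'   that is allowed (performance above baseline), not an error.
#' @examples
#' suppression_ratio(c(0.2, 0.6), baseline = 0.76)
#' @export
suppression_ratio <- function(t2_given_t1, baseline,
                              form = c("deficit", "ratio")) {
  form <- match.arg(form)
  stopifnot(is.numeric(t2_given_t1), is.numeric(baseline))
  if (any(baseline <= 0)) {
    stop("`baseline` must be strictly positive", call. = FALSE)
  }
  if (form == "deficit") (baseline - t2_given_t1) / baseline
  else t2_given_t1 / baseline
}

#' Baseline accuracy from an accuracy-by-lag curve
#'
#' The single-target baseline `Pr(T1)` is estimated as the mean accuracy of
#' the two largest lags, where accuracy has returned to its asymptote.
#'
#' @param curve data frame with columns `lag` and `value`, or a numeric
#'   vector ordered by increasing lag.
#' @return scalar baseline estimate.
#' @export
baseline_from_curve <- function(curve) {
  values <- if (is.data.frame(curve)) {
    stopifnot(all(c("lag", "value") %in% names(curve)))
    curve$value[order(curve$lag)]
  } else {
    as.numeric(curve)
  }
  n <- length(values)
  if (n < 2L) stop("need at least 2 lags to estimate a baseline",
                   call. = FALSE)
  mean(values[c(n - 1L, n)])
}

#' Monte-Carlo study of the suppression-ratio interaction artifact
#'
#' Simulates a two-group cohort in which the patient group differs from
#' control only by a baseline shift -- the null hypothesis of equal blink
#' depth holds by construction -- then analyses the same simulated data
#' twice: on the raw accuracies and after the per-subject suppression-ratio
#' transform. A spurious group-by-lag interaction in the transformed
#' analysis, absent from the raw one, is the artifact.
#'
#' @inheritParams simulate_cohort
#' @param alpha significance level for the per-lag simple-effect tests.
#' @param sr_form passed to [suppression_ratio()].
#' @param sr_baseline `"subject"` (default) computes each subject's own
#'   last-two-lags baseline; `"group"` uses the group mean baseline.
#' @param clip clip simulated accuracies to `[0, 1]`? Default `FALSE`
#'   so the uniform noise is uncensored and the raw-data null is exact.
#' @return list of class `artifact_study` with elements `anova_raw`,
#'   `anova_sr` (see [mixed_anova()]), `per_lag_raw`, `per_lag_sr` (data
#'   frames of per-lag two-sample t tests), `n_per_group`, `seed`.
#' @export
run_artifact_study <- function(control, baseline_offset, n_per_group, lags,
                               seed, alpha = 0.05,
                               sr_form = c("deficit", "ratio"),
                               sr_baseline = c("subject", "group"),
                               clip = FALSE) {
  sr_form <- match.arg(sr_form)
  sr_baseline <- match.arg(sr_baseline)
  raw <- simulate_cohort(control, baseline_offset, n_per_group, lags,
                         seed = seed, clip = clip)

  sr <- raw
  if (sr_baseline == "subject") {
    for (sid in unique(sr$subject_id)) {
      idx <- sr$subject_id == sid
      b <- baseline_from_curve(sr[idx, c("lag", "value")])
      sr$value[idx] <- suppression_ratio(sr$value[idx], b, form = sr_form)
    }
  } else {
    for (g in levels(sr$group)) {
      idx <- sr$group == g
      gm <- stats::aggregate(value ~ lag, data = sr[idx, ], FUN = mean)
      b <- baseline_from_curve(data.frame(lag = gm$lag, value = gm$value))
      sr$value[idx] <- suppression_ratio(sr$value[idx], b, form = sr_form)
    }
  }

  structure(list(
    anova_raw = mixed_anova(raw),
    anova_sr = mixed_anova(sr),
    per_lag_raw = simple_effects(raw, alpha = alpha),
    per_lag_sr = simple_effects(sr, alpha = alpha),
    n_per_group = n_per_group,
    seed = seed
  ), class = "artifact_study")
}

#' Rejection rates of each ANOVA effect across seeded replicates
#'
#' Repeats [run_artifact_study()] `n_replicates` times with per-replicate
#' seeds derived from `seed`, and tabulates how often each effect (group,
#' lag, interaction) rejects at `alpha` in the raw and suppression-ratio
#' analyses, with exact (Clopper-Pearson) binomial confidence intervals.
#'
#' @param control,baseline_offset,n_per_group,lags,alpha,sr_form,clip as in
#'   [run_artifact_study()].
#' @param n_replicates number of Monte-Carlo replicates, at least 1.
#' @param seed master seed.
#' @param conf_level confidence level for the binomial intervals.
#' @return list with `rates`, a data frame with columns `transform`
#'   (`raw`/`sr`), `effect`, `rejections`, `n_replicates`, `rate`,
#'   `ci_lower`, `ci_upper`; and `p_values`, the per-replicate p-value
#'   table (columns `replicate`, `transform`, `effect`, `p`).
#' @export
replicate_artifact_power <- function(control, baseline_offset, n_per_group,
                                     lags, n_replicates, seed,
                                     alpha = 0.05,
                                     sr_form = c("deficit", "ratio"),
                                     clip = FALSE,
                                     conf_level = 0.99) {
  stopifnot(n_replicates >= 1)
  sr_form <- match.arg(sr_form)
  effects <- c("group", "lag", "group:lag")
  pvals <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    st <- run_artifact_study(control, baseline_offset, n_per_group, lags,
                             seed = split_seed(seed, r), alpha = alpha,
                             sr_form = sr_form, clip = clip)
    pvals[[r]] <- data.frame(
      replicate = r,
      transform = rep(c("raw", "sr"), each = length(effects)),
      effect = rep(effects, 2L),
      p = c(st$anova_raw$p[match(effects, st$anova_raw$effect)],
            st$anova_sr$p[match(effects, st$anova_sr$effect)])
    )
  }
  p_values <- do.call(rbind, pvals)
  rates <- do.call(rbind, lapply(split(
    p_values, list(p_values$transform, p_values$effect)
  ), function(d) {
    k <- sum(d$p < alpha)
    ci <- stats::binom.test(k, n_replicates,
                            conf.level = conf_level)$conf.int
    data.frame(transform = d$transform[1], effect = d$effect[1],
               rejections = k, n_replicates = n_replicates,
               rate = k / n_replicates,
               ci_lower = ci[1], ci_upper = ci[2])
  }))
  rownames(rates) <- NULL
  list(rates = rates, p_values = p_values)
}
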