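test_that("decay laws hit their closed-form anchors and limits", {
  expect_equal(decay_value("EDF", 1.3, 0.03, 1), exp(-1.3) + 0.03,
               tolerance = 1e-12)
  expect_equal(decay_value("EDF", 1.3, 0.03, 1), 0.30253, tolerance = 1e-5)
  # both laws settle onto the baseline far out
  expect_lt(abs(decay_value("EDF", 1.3, 0.03, 50) - 0.03), 1e-9)
  expect_lt(abs(decay_value("LDF", 1.4, 0.06, 50) - 0.06), 1e-9)
  # documented x -> 0 anchors of the default forms
  expect_equal(decay_value("EDF", 2, 0.1, 1e-12), 1.1, tolerance = 1e-9)
  expect_equal(decay_value("LDF", 2, 0.1, 1e-12), 0.6, tolerance = 1e-9)
})

test_that("decay laws decrease strictly and converge to baseline", {
  x <- seq(0.5, 12, by = 0.25)
  for (k in c("EDF", "LDF")) {
    for (a in c(0.7, 1.3, 2.5)) {
      v <- decay_value(k, a, 0.05, x)
      expect_true(all(diff(v) < 0))
      expect_true(all(v > 0.05))
    }
  }
})

test_that("fit_decay recovers noise-free generating parameters", {
  lags <- c(1, 2, 3, 4, 6, 8, 12)
  curve <- data.frame(lag = lags, value = decay_value("EDF", 1.3, 0.03,
                                                      lags))
  fit <- fit_decay(curve, "EDF")
  expect_equal(fit$decay_rate, 1.3, tolerance = 1e-4)
  expect_equal(fit$baseline, 0.03, tolerance = 1e-4)
  expect_lt(fit$mse, 1e-10)

  curve_l <- data.frame(lag = lags, value = decay_value("LDF", 1.4, 0.06,
                                                        lags))
  fit_l <- fit_decay(curve_l, "LDF")
  expect_equal(fit_l$decay_rate, 1.4, tolerance = 1e-4)
  expect_equal(fit_l$baseline, 0.06, tolerance = 1e-4)
})

test_that("model mismatch costs MSE in the expected direction", {
  lags <- c(1, 2, 3, 4, 6, 8, 12)
  curve_l <- data.frame(lag = lags, value = decay_value("LDF", 1.4, 0.06,
                                                        lags))
  fit_right <- fit_decay(curve_l, "LDF")
  fit_wrong <- fit_decay(curve_l, "EDF")
  expect_gt(fit_wrong$mse, fit_right$mse)
})

test_that("fit_decay agrees with a 2-D grid-search oracle", {
  lags <- c(1, 2, 3, 4, 6, 8, 12)
  set.seed(41)
  curve <- data.frame(
    lag = lags,
    value = decay_value("EDF", 1.7, 0.08, lags) + rnorm(7, 0, 0.01)
  )
  fit <- fit_decay(curve, "EDF")
  a_grid <- seq(1e-3, 5, by = 1e-3)
  # vectorised exhaustive search: for each a, the best baseline is the
  # mean residual (linear in b), so profile b out exactly
  E <- exp(-outer(a_grid, lags)) # len(a) x len(lags)
  resid0 <- matrix(curve$value, nrow = length(a_grid), ncol = 7,
                   byrow = TRUE) - E
  b_star <- pmin(0.5, pmax(0, rowMeans(resid0)))
  sse <- rowSums((resid0 - b_star)^2)
  i <- which.min(sse)
  expect_lt(abs(fit$decay_rate - a_grid[i]), 1e-3 + 1e-9)
  expect_lt(abs(fit$baseline - b_star[i]), 1e-3)
  expect_lte(fit$mse, sse[i] / 7 + 1e-12)
})

test_that("group comparison picks each group's generating law, noise-free", {
  lags <- c(0.5, 1, 1.5, 2, 3, 4, 6)
  gen <- list(
    patient = list(kind = "EDF", a = 1.3, b = 0.03),
    control = list(kind = "LDF", a = 1.4, b = 0.06),
    spd     = list(kind = "LDF", a = 1.4, b = 0.06),
    nonspd  = list(kind = "LDF", a = 1.4, b = 0.04)
  )
  curves <- lapply(gen, function(g) {
    data.frame(lag = lags, value = decay_value(g$kind, g$a, g$b, lags))
  })
  rep <- compare_decay_models(curves)
  for (g in names(gen)) {
    winner <- rep$kind[rep$group == g & rep$winner]
    expect_equal(winner, gen[[g]]$kind)
  }
  # identical input curves give identical fits
  two <- compare_decay_models(list(x = curves$patient, y = curves$patient))
  expect_equal(two$mse[two$group == "x"], two$mse[two$group == "y"])
  expect_equal(two$decay_rate[two$group == "x"],
               two$decay_rate[two$group == "y"])
  # winner decision equals an independent recomputation of both MSEs
  for (g in names(gen)) {
    sub <- rep[rep$group == g, ]
    mse_re <- vapply(seq_len(nrow(sub)), function(i) {
      mean((curves[[g]]$value -
              decay_value(sub$kind[i], sub$decay_rate[i], sub$baseline[i],
                          lags))^2)
    }, numeric(1))
    expect_equal(sub$winner, mse_re == min(mse_re))
  }
})

test_that("model selection is consistent under low noise", {
  # fine TOA grid including the sub-100 ms lag, where the two laws are
  # most separable (EDF anchors at b+1 as x -> 0, LDF at b+0.5)
  lags <- c(0.5, 1, 1.5, 2, 3, 4, 6)
  n_rep <- 100
  set.seed(61)
  for (gen_kind in c("EDF", "LDF")) {
    correct <- 0
    for (r in seq_len(n_rep)) {
      v <- decay_value(gen_kind, 1.5, 0.05, lags) + rnorm(7, 0, 0.01)
      curve <- data.frame(lag = lags, value = v)
      mses <- c(EDF = fit_decay(curve, "EDF")$mse,
                LDF = fit_decay(curve, "LDF")$mse)
      correct <- correct + (names(which.min(mses)) == gen_kind)
    }
    expect_gte(correct / n_rep, 0.95)
  }
})

test_that("per-subject rates recover generating rates across a cohort", {
  set.seed(23)
  lags <- c(1, 2, 3, 4, 6, 8, 12)
  n <- 24
  # between-patient decay-rate spread: lognormal around the group rate
  # with ~40% coefficient of variation
  true_rates <- exp(rnorm(n, log(1.3), 0.4))
  curves <- do.call(rbind, lapply(seq_len(n), function(i) {
    tru <- data.frame(lag = lags, pr_t1 = 0.95, pr_t2_given_t1 = 0.9,
                      pr_swap = pmin(0.8, decay_value("EDF", true_rates[i],
                                                      0.03, lags)))
    prot <- protocol_spec(toas_ms = as.integer(lags * 100),
                          soa_by_group = c(g = 100L),
                          trials_per_toa = 100L, n_per_group = 2)
    trs <- generate_trials(tru, prot, seed = 5000 + i,
                           subject_id = sprintf("s%02d", i))
    aggregate_trials(trs)
  }))
  rates <- subject_decay_rates(curves, kind = "EDF")
  expect_equal(nrow(rates), n)
  expect_gt(cor(rates$decay_rate, true_rates), 0.9)
})

test_that("all-zero swap curves are reported missing, not fatal", {
  lags <- c(1, 2, 3, 4)
  curves <- rbind(
    data.frame(subject_id = "ok", lag = lags,
               pr_swap = decay_value("EDF", 1.3, 0.03, lags)),
    data.frame(subject_id = "flat", lag = lags, pr_swap = 0)
  )
  expect_warning(rates <- subject_decay_rates(curves), "unidentifiable")
  expect_equal(sum(is.na(rates$decay_rate)), 1L)
  expect_equal(rates$subject_id[is.na(rates$decay_rate)], "flat")
})

test_that("clinical correlation matches the covariance-formula oracle", {
  set.seed(11)
  n <- 24
  rates <- data.frame(subject_id = sprintf("p%02d", 1:n),
                      decay_rate = exp(rnorm(n, 0.3, 0.2)))
  clin <- data.frame(subject_id = sprintf("p%02d", 1:n),
                     panss_positive = round(rnorm(n, 9, 3)))
  got <- correlate_decay_with_clinical(rates, clin, "panss_positive")
  # independent formula: r from covariance, p via the t transform
  x <- rates$decay_rate; y <- clin$panss_positive
  r_o <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_o <- r_o * sqrt((n - 2) / (1 - r_o^2))
  p_o <- 2 * pt(abs(t_o), n - 2, lower.tail = FALSE)
  expect_equal(got$r, r_o, tolerance = 1e-12)
  expect_equal(got$p, p_o, tolerance = 1e-12)
  expect_equal(got$df, 22)

  # perfect proportionality and affine invariance
  clin2 <- data.frame(subject_id = rates$subject_id,
                      panss_positive = 3 * rates$decay_rate + 2)
  expect_equal(
    correlate_decay_with_clinical(rates, clin2, "panss_positive")$r, 1,
    tolerance = 1e-12
  )
  clin3 <- clin
  clin3$panss_positive <- 10 * clin$panss_positive - 4
  expect_equal(
    correlate_decay_with_clinical(rates, clin3, "panss_positive")$r,
    got$r, tolerance = 1e-12
  )
})

test_that("degenerate correlation inputs error informatively", {
  rates <- data.frame(subject_id = c("a", "b", "c", "d"),
                      decay_rate = c(1, 1, 1, 1))
  clin <- data.frame(subject_id = c("a", "b", "c", "d"),
                     panss_positive = 1:4)
  expect_error(correlate_decay_with_clinical(rates, clin,
                                             "panss_positive"),
               "zero variance")
  expect_error(
    correlate_decay_with_clinical(rates[1:3, ], clin[1:3, ],
                                  "panss_positive"),
    "at least 4"
  )
})
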