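test_that("protocol presets encode both experimental designs", {
  e1 <- protocol_spec(preset = "exp1")
  expect_equal(e1$toas_ms, c(100L, 200L, 300L, 400L, 600L, 800L, 1200L))
  expect_equal(e1$soa_by_group, c(patient = 100L, control = 50L))
  expect_equal(e1$n_per_group, 24L)
  expect_equal(e1$dual_target_fraction, 0.75)

  e2 <- protocol_spec(preset = "exp2")
  expect_equal(e2$toas_ms, c(50L, 100L, 150L, 200L, 300L, 400L, 600L))
  expect_equal(unname(e2$soa_by_group), c(50L, 50L))
  expect_equal(e2$n_per_group, 25L)
})

test_that("protocol validation enforces timing and pool constraints", {
  expect_error(
    protocol_spec(toas_ms = c(150L, 300L), soa_by_group = c(g = 100L),
                  n_per_group = 4),
    "divisible"
  )
  expect_error(
    protocol_spec(toas_ms = c(100L, 200L), soa_by_group = c(g = 100L),
                  n_per_group = 4, target_pool = c("A", "2"),
                  distractor_pool = LETTERS[1:4]),
    "disjoint"
  )
  expect_error(protocol_spec(preset = "exp3"), "arg")
})

test_that("subject truth composes curves and decay with known anchors", {
  t1 <- gamma_ab_params(2.1, 0.96, 1, 0, noise_halfwidth = 0)
  t2 <- gamma_ab_params(2.1, 0.96, 1, 0, noise_halfwidth = 0)
  swap <- list(kind = "EDF", decay_rate = 1.3, baseline = 0.03)
  tru <- generate_subject_truth(t1, t2, swap, lags = c(1, 2, 4), seed = 1)
  expect_equal(tru$pr_swap[1], exp(-1.3) + 0.03, tolerance = 1e-12)
  expect_equal(tru$pr_t1, rep(1, 3))
  # limit: huge decay rate and zero baseline kill swaps
  swap0 <- list(kind = "EDF", decay_rate = 9.9, baseline = 0)
  tru0 <- generate_subject_truth(t1, t2, swap0, lags = c(1, 2, 4), seed = 1)
  expect_true(all(tru0$pr_swap < 1e-4))
  # determinism
  p <- default_group_params("patient")
  a <- generate_subject_truth(p$t1_curve, p$t2_curve, p$swap_decay, 1:8, 7)
  b <- generate_subject_truth(p$t1_curve, p$t2_curve, p$swap_decay, 1:8, 7)
  expect_identical(a, b)
  # swap never exceeds what both-report feasibility allows
  expect_true(all(a$pr_swap <= a$pr_t1 * a$pr_t2_given_t1 + 1e-12))
})

test_that("perfect probabilities yield veridical dual reports", {
  tru <- data.frame(lag = c(1, 3), pr_t1 = 1, pr_t2_given_t1 = 1,
                    pr_swap = 0)
  prot <- protocol_spec(toas_ms = c(100L, 300L), soa_by_group = c(g = 100L),
                        trials_per_toa = 20L, n_per_group = 2)
  trs <- generate_trials(tru, prot, seed = 2)
  dual <- trs[trs$condition == "dual", ]
  expect_true(all(dual$report_1 == dual$t1))
  expect_true(all(dual$report_2 == dual$t2))
  expect_true(all(dual$t1 != dual$t2))
})

test_that("trial outcomes hit their generating rates within binomial error", {
  tru <- data.frame(lag = 1, pr_t1 = 0.8, pr_t2_given_t1 = 0.6,
                    pr_swap = 0.2)
  prot <- protocol_spec(toas_ms = 100L, soa_by_group = c(g = 100L),
                        trials_per_toa = 10000L, n_per_group = 2)
  trs <- generate_trials(tru, prot, seed = 5)
  agg <- aggregate_trials(trs)
  expect_lt(abs(agg$pr_t1 - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  expect_lt(abs(agg$pr_t2_given_t1 - 0.6),
            3 * sqrt(0.6 * 0.4 / (10000 * 0.8)))
  expect_lt(abs(agg$pr_swap - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
})

test_that("catch-trial count honours the dual-target fraction", {
  tru <- data.frame(lag = 1, pr_t1 = 0.9, pr_t2_given_t1 = 0.9,
                    pr_swap = 0.05)
  prot <- protocol_spec(toas_ms = 100L, soa_by_group = c(g = 100L),
                        trials_per_toa = 750L, n_per_group = 2)
  trs <- generate_trials(tru, prot, seed = 6)
  n_triple <- sum(trs$condition == "triple")
  expect_lt(abs(n_triple - 250), 3 * sqrt(1000 * 0.75 * 0.25))
  # triple trials always carry a third target identity
  expect_true(all(trs$t3[trs$condition == "triple"] != ""))
  expect_true(all(trs$t3[trs$condition == "dual"] == ""))
})

test_that("infeasible swap rates are capped with a warning", {
  tru <- data.frame(lag = 1, pr_t1 = 0.5, pr_t2_given_t1 = 0.5,
                    pr_swap = 0.9)
  prot <- protocol_spec(toas_ms = 100L, soa_by_group = c(g = 100L),
                        trials_per_toa = 10L, n_per_group = 2)
  expect_warning(generate_trials(tru, prot, seed = 1), "capped")
})

test_that("build_study presets produce the documented cohorts", {
  st <- build_study("exp1", seed = 42)
  expect_equal(length(unique(st$trials$subject_id)), 48)
  expect_equal(sort(unique(st$trials$toa_ms)),
               c(100L, 200L, 300L, 400L, 600L, 800L, 1200L))
  expect_equal(st$manifest$soa_by_group$patient, 100L)
  expect_equal(st$manifest$soa_by_group$control, 50L)
  expect_setequal(unique(st$truth$group), c("patient", "control"))

  st2 <- build_study("exp2", seed = 42)
  expect_equal(length(unique(st2$trials$subject_id)), 50)
  expect_equal(st2$manifest$soa_by_group$spd, 50L)
  expect_equal(st2$manifest$soa_by_group$nonspd, 50L)
})

test_that("identical seeds give byte-identical study files", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  prot <- protocol_spec(toas_ms = c(100L, 200L), soa_by_group = c(g = 100L),
                        trials_per_toa = 5L, n_per_group = 2)
  build_study(prot, seed = 9, out_dir = d1)
  build_study(prot, seed = 9, out_dir = d2)
  for (f in c("trials.csv", "truth.csv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("adding subjects never perturbs existing subjects' streams", {
  prot_small <- protocol_spec(toas_ms = c(100L, 200L),
                              soa_by_group = c(g = 100L),
                              trials_per_toa = 5L, n_per_group = 2)
  prot_big <- protocol_spec(toas_ms = c(100L, 200L),
                            soa_by_group = c(g = 100L),
                            trials_per_toa = 5L, n_per_group = 4)
  small <- build_study(prot_small, seed = 77)
  big <- build_study(prot_big, seed = 77)
  shared <- small$truth$subject_id
  expect_equal(small$truth,
               big$truth[big$truth$subject_id %in% shared, ],
               ignore_attr = TRUE)
})

test_that("aggregation reproduces a hand-counted four-trial example", {
  # both-correct-ordered, both-correct-reversed, T1-only, neither
  trials <- data.frame(
    subject_id = "s1", group = "g", trial_index = 1:4,
    condition = "dual", toa_ms = 300L,
    t1 = "3", t2 = "7", t3 = "",
    report_1 = c("3", "7", "3", ""),
    report_2 = c("7", "3", "", ""),
    report_3 = ""
  )
  agg <- aggregate_trials(trials)
  expect_equal(agg$pr_t1, 0.75)
  expect_equal(agg$pr_t2_given_t1, 2 / 3)
  expect_equal(agg$pr_swap, 0.25)
  expect_equal(agg$lag, 3)
})

test_that("triple-target trials never enter aggregated curves", {
  trials <- data.frame(
    subject_id = "s1", group = "g", trial_index = 1:4,
    condition = c("dual", "dual", "triple", "triple"), toa_ms = 300L,
    t1 = "3", t2 = "7", t3 = c("", "", "5", "5"),
    report_1 = c("3", "3", "", ""), report_2 = c("7", "7", "", ""),
    report_3 = ""
  )
  agg <- aggregate_trials(trials)
  expect_equal(agg$n_trials, 2L)
  expect_equal(agg$pr_t1, 1)
})

test_that("round trip: high-count aggregation recovers the truth profile", {
  tru <- data.frame(lag = c(1, 2, 3),
                    pr_t1 = c(0.8, 0.85, 0.9),
                    pr_t2_given_t1 = c(0.5, 0.7, 0.85),
                    pr_swap = c(0.25, 0.1, 0.03))
  prot <- protocol_spec(toas_ms = c(100L, 200L, 300L),
                        soa_by_group = c(g = 100L),
                        trials_per_toa = 50000L, n_per_group = 2)
  agg <- aggregate_trials(generate_trials(tru, prot, seed = 3))
  m <- merge(agg, tru, by = "lag", suffixes = c("", "_true"))
  dev <- max(abs(m$pr_t1 - m$pr_t1_true),
             abs(m$pr_t2_given_t1 - m$pr_t2_given_t1_true),
             abs(m$pr_swap - m$pr_swap_true))
  expect_lt(dev, 0.01)
})

test_that("aggregation names subjects with empty cells", {
  trials <- data.frame(
    subject_id = c("s1", "s1", "s2"), group = "g", trial_index = 1:3,
    condition = "dual", toa_ms = c(100L, 200L, 100L),
    t1 = "3", t2 = "7", t3 = "",
    report_1 = "3", report_2 = "7", report_3 = ""
  )
  expect_error(aggregate_trials(trials), "s2")
})
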