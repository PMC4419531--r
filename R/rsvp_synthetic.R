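#' Protocol specification for a synthetic dual-target RSVP study
#'
#' Describes the timing and design of one experiment: the grid of T1-T2
#' onset asynchronies (TOAs), the per-group stimulus onset asynchrony
#' (SOA), the fraction of dual-target trials (the remainder are
#' triple-target catch trials, excluded from analysis), the number of
#' trials per TOA, and the target/distractor symbol pools.
#'
#' Presets mirror the two study designs:
#' \itemize{
#'   \item `"exp1"`: TOAs 100-1200 ms, SOA 100 ms for patients and 50 ms
#'     for controls (rate titrated to match baseline perception), 24
#'     subjects per group.
#'   \item `"exp2"`: TOAs 50-600 ms, SOA 50 ms for both groups (SPD vs
#'     non-SPD), 25 subjects per group.
#' }
#'
#' @param preset `"exp1"`, `"exp2"`, or `NULL` to specify fields directly.
#' @param toas_ms increasing integer vector of TOAs in ms.
#' @param soa_by_group named integer vector, SOA in ms per group label.
#' @param dual_target_fraction fraction of dual-target trials in `(0, 1]`;
#'   default 0.75.
#' @param trials_per_toa dual-target trials per TOA per subject.
#' @param n_per_group subjects per group.
#' @param target_pool,distractor_pool disjoint symbol vectors; defaults are
#'   8 digits and 16 capital letters.
#' @return list of class `protocol_spec`.
#' @export
protocol_spec <- function(preset = NULL,
                          toas_ms = NULL,
                          soa_by_group = NULL,
                          dual_target_fraction = 0.75,
                          trials_per_toa = 30L,
                          n_per_group = NULL,
                          target_pool = as.character(2:9),
                          distractor_pool = LETTERS[1:16]) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("exp1", "exp2"))
    if (preset == "exp1") {
      toas_ms <- c(100L, 200L, 300L, 400L, 600L, 800L, 1200L)
      soa_by_group <- c(patient = 100L, control = 50L)
      if (is.null(n_per_group)) n_per_group <- 24L
    } else {
      toas_ms <- c(50L, 100L, 150L, 200L, 300L, 400L, 600L)
      soa_by_group <- c(spd = 50L, nonspd = 50L)
      if (is.null(n_per_group)) n_per_group <- 25L
    }
  }
  if (is.null(toas_ms) || is.null(soa_by_group) || is.null(n_per_group)) {
    stop("either a preset or toas_ms, soa_by_group and n_per_group ",
         "must be given", call. = FALSE)
  }
  stopifnot(!is.unsorted(toas_ms, strictly = TRUE), all(toas_ms > 0),
            dual_target_fraction > 0, dual_target_fraction <= 1,
            trials_per_toa >= 1, n_per_group >= 2,
            !is.null(names(soa_by_group)))
  for (g in names(soa_by_group)) {
    if (any(toas_ms %% soa_by_group[[g]] != 0L)) {
      stop("all TOAs must be divisible by the SOA of group '", g,
           "' (", soa_by_group[[g]], " ms) for lag-position placement",
           call. = FALSE)
    }
  }
  if (length(intersect(target_pool, distractor_pool)) > 0L) {
    stop("target and distractor pools must be disjoint", call. = FALSE)
  }
  structure(list(
    toas_ms = as.integer(toas_ms),
    soa_by_group = soa_by_group,
    dual_target_fraction = dual_target_fraction,
    trials_per_toa = as.integer(trials_per_toa),
    n_per_group = as.integer(n_per_group),
    target_pool = target_pool,
    distractor_pool = distractor_pool
  ), class = "protocol_spec")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate one subject's true per-lag probability profile
#'
#' Composes the generative pieces into a per-subject "truth" record: T1 and
#' conditional T2 accuracies from (optionally noisy) inverted-gamma AB
#' curves, and swap probability from a decay law plus uniform subject
#' noise. All probabilities are clipped to `[0, 1]` and the swap
#' probability is additionally capped at `pr_t1 * pr_t2_given_t1` (a swap
#' requires both targets reported).
#'
#' @param t1_curve,t2_curve [gamma_ab_params()] for T1 accuracy and
#'   conditional T2 accuracy.
#' @param swap_decay list with `kind` (`"EDF"`/`"LDF"`), `decay_rate`,
#'   `baseline`, and optionally `noise_halfwidth` (default 0) for uniform
#'   per-lag subject noise on the swap curve.
#' @param lags lag grid (TOA / 100 ms).
#' @param seed integer seed.
#' @return data frame with columns `lag`, `pr_t1`, `pr_t2_given_t1`,
#'   `pr_swap`.
#' @export
generate_subject_truth <- function(t1_curve, t2_curve, swap_decay, lags,
                                   seed) {
  assert_lags(lags)
  stopifnot(all(c("kind", "decay_rate", "baseline") %in% names(swap_decay)))
  p1 <- simulate_subject_curve(t1_curve, lags, seed = split_seed(seed, 1L))
  p2 <- simulate_subject_curve(t2_curve, lags, seed = split_seed(seed, 2L))
  swap <- decay_value(swap_decay$kind, swap_decay$decay_rate,
                      swap_decay$baseline, lags)
  nh <- swap_decay$noise_halfwidth %||% 0
  if (nh > 0) {
    swap <- swap + with_seed(split_seed(seed, 3L),
                             stats::runif(length(lags), -nh, nh))
  }
  pr_t1 <- clip01(p1$value)
  pr_t2 <- clip01(p2$value)
  pr_swap <- pmin(clip01(swap), pr_t1 * pr_t2)
  data.frame(lag = as.numeric(lags), pr_t1 = pr_t1,
             pr_t2_given_t1 = pr_t2, pr_swap = pr_swap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate trial-level RSVP records for one subject
#'
#' For each dual-target trial at TOA `tau`: T1 is reported with probability
#' `pr_t1(tau)`; conditional on T1, T2 is reported with
#' `pr_t2_given_t1(tau)`; given both are reported, their order is reversed
#' with probability `pr_swap / (pr_t1 * pr_t2_given_t1)` (capped at 1 with
#' a warning if infeasible) so the marginal swap rate matches the truth
#' where feasible. Triple-target catch trials carry a third target 800 ms
#' after T2 and are flagged by `condition = "triple"` for exclusion.
#' Target identities are drawn uniformly without replacement from the
#' protocol's target pool.
#'
#' @param truth data frame from [generate_subject_truth()]; rows must
#'   cover `protocol$toas_ms / 100`.
#' @param protocol a [protocol_spec()].
#' @param seed integer seed.
#' @param subject_id,group labels stamped on the records.
#' @return data frame with columns `subject_id`, `group`, `trial_index`,
#'   `condition` (`dual`/`triple`), `toa_ms`, `t1`, `t2`, `t3`,
#'   `report_1`, `report_2`, `report_3` (empty string for absent items).
#' @export
generate_trials <- function(truth, protocol, seed, subject_id = "s01",
                            group = names(protocol$soa_by_group)[1]) {
  stopifnot(inherits(protocol, "protocol_spec"))
  lags <- protocol$toas_ms / 100
  if (!all(lags %in% truth$lag)) {
    stop("truth profile lacks lags: ",
         paste(setdiff(lags, truth$lag), collapse = ", "), call. = FALSE)
  }
  n_dual <- protocol$trials_per_toa
  # catch trials top the design up to the stated dual fraction
  n_triple_total <- round(n_dual * length(lags) *
                            (1 - protocol$dual_target_fraction) /
                            protocol$dual_target_fraction)
  with_seed(seed, {
    blocks <- vector("list", length(lags) + 1L)
    for (li in seq_along(lags)) {
      l <- lags[li]
      tr <- truth[truth$lag == l, ]
      p_both <- tr$pr_t1 * tr$pr_t2_given_t1
      p_swap_cond <- if (p_both > 0) tr$pr_swap / p_both else 0
      if (p_swap_cond > 1) {
        warning("infeasible swap rate at lag ", l,
                " (pr_swap > pr_t1*pr_t2|t1); capped", call. = FALSE)
        p_swap_cond <- 1
      }
      n <- n_dual
      # two distinct identities per trial, uniform over the target pool
      id1 <- sample(protocol$target_pool, n, replace = TRUE)
      shift <- sample.int(length(protocol$target_pool) - 1L, n,
                          replace = TRUE)
      id2 <- protocol$target_pool[
        (match(id1, protocol$target_pool) - 1L + shift) %%
          length(protocol$target_pool) + 1L
      ]
      t1_rep <- stats::runif(n) < tr$pr_t1
      t2_rep <- t1_rep & stats::runif(n) < tr$pr_t2_given_t1
      swapped <- t2_rep & stats::runif(n) < p_swap_cond
      both <- t1_rep & t2_rep
      report_1 <- ifelse(both, ifelse(swapped, id2, id1),
                         ifelse(t1_rep, id1, ""))
      report_2 <- ifelse(both, ifelse(swapped, id1, id2), "")
      blocks[[li]] <- data.frame(
        subject_id = subject_id, group = group, trial_index = 0L,
        condition = "dual", toa_ms = as.integer(l * 100),
        t1 = id1, t2 = id2, t3 = "",
        report_1 = report_1, report_2 = report_2, report_3 = ""
      )
    }
    if (n_triple_total > 0L) {
      tau <- sample(protocol$toas_ms, n_triple_total, replace = TRUE)
      tr <- truth[match(tau / 100, truth$lag), ]
      n <- n_triple_total
      pool <- protocol$target_pool
      id1 <- sample(pool, n, replace = TRUE)
      s1 <- sample.int(length(pool) - 1L, n, replace = TRUE)
      id2 <- pool[(match(id1, pool) - 1L + s1) %% length(pool) + 1L]
      id3 <- vapply(seq_len(n), function(i)
        sample(setdiff(pool, c(id1[i], id2[i])), 1L), character(1))
      t1_rep <- stats::runif(n) < tr$pr_t1
      t2_rep <- t1_rep & stats::runif(n) < tr$pr_t2_given_t1
      # third target sits 800 ms after T2, outside the blink
      t3_rep <- stats::runif(n) < tr$pr_t1
      r1 <- ifelse(t1_rep, id1, ifelse(t2_rep, id2,
                                       ifelse(t3_rep, id3, "")))
      r2 <- ifelse(t1_rep & t2_rep, id2,
                   ifelse((t1_rep | t2_rep) & t3_rep, id3, ""))
      r3 <- ifelse(t1_rep & t2_rep & t3_rep, id3, "")
      blocks[[length(lags) + 1L]] <- data.frame(
        subject_id = subject_id, group = group, trial_index = 0L,
        condition = "triple", toa_ms = as.integer(tau),
        t1 = id1, t2 = id2, t3 = id3,
        report_1 = r1, report_2 = r2, report_3 = r3
      )
    }
    out <- do.call(rbind, blocks)
    out$trial_index <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  })
}

#' Default generative parameters for the synthetic studies
#'
#' Per-group generative settings used by [build_study()]: conditional T2
#' accuracy follows the fitted control curve (shape 2.1, scale 0.96,
#' baseline 0.86, depth 0.87) in every group -- equal blink depth, the
#' finding the synthetic studies emulate -- T1 accuracy a shallower dip
#' (depth 0.25) with the same timing, and swap curves the per-group decay
#' laws and parameters of the published model-comparison table (patients
#' EDF 1.3/0.03; controls LDF 1.4/0.06; SPD LDF 1.4/0.06; non-SPD LDF
#' 1.4/0.04). Subject noise half-widths default to 0.05 so that
#' between-subject spread rides on top of trial-level binomial noise.
#'
#' @param group group label (`patient`, `control`, `spd`, `nonspd`).
#' @param subject_noise uniform half-width for the accuracy curves.
#' @return list with `t1_curve`, `t2_curve`, `swap_decay`.
#' @export
default_group_params <- function(group = c("patient", "control", "spd",
                                           "nonspd"),
                                 subject_noise = 0.05) {
  group <- match.arg(group)
  swap <- switch(group,
    patient = list(kind = "EDF", decay_rate = 1.3, baseline = 0.03),
    control = list(kind = "LDF", decay_rate = 1.4, baseline = 0.06),
    spd     = list(kind = "LDF", decay_rate = 1.4, baseline = 0.06),
    nonspd  = list(kind = "LDF", decay_rate = 1.4, baseline = 0.04)
  )
  swap$noise_halfwidth <- 0.02
  list(
    t1_curve = gamma_ab_params(2.1, 0.96, 0.9, 0.25,
                               noise_halfwidth = subject_noise),
    t2_curve = gamma_ab_params(2.1, 0.96, 0.86, 0.87,
                               noise_halfwidth = subject_noise),
    swap_decay = swap
  )
}

#' Build a full synthetic study (trials + truth for both groups)
#'
#' Generates the complete trial-level dataset for a two-group study from a
#' preset or explicit protocol, with per-subject random streams split from
#' the master seed so that adding subjects never perturbs existing ones.
#'
#' @param protocol a [protocol_spec()] or preset name (`"exp1"`/`"exp2"`).
#' @param seed master integer seed.
#' @param group_params optional named list mapping each group label to a
#'   list as returned by [default_group_params()]; defaults are filled in
#'   by group label.
#' @param out_dir optional directory; when given, writes `trials.csv`,
#'   `truth.csv` and `manifest.json` (seed, protocol, file hashes) there.
#' @return list with data frames `trials` and `truth` (the latter in long
#'   format: `subject_id`, `group`, `lag`, `pr_t1`, `pr_t2_given_t1`,
#'   `pr_swap`), and `manifest`.
#' @export
build_study <- function(protocol, seed, group_params = NULL,
                        out_dir = NULL) {
  if (is.character(protocol)) protocol <- protocol_spec(preset = protocol)
  stopifnot(inherits(protocol, "protocol_spec"))
  groups <- names(protocol$soa_by_group)
  lags <- protocol$toas_ms / 100
  trials <- list()
  truth <- list()
  k <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    gp <- group_params[[g]] %||% default_group_params(
      if (g %in% c("patient", "control", "spd", "nonspd")) g else "control"
    )
    for (i in seq_len(protocol$n_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s_%03d", g, i)
      s_seed <- split_seed(seed, k)
      tru <- generate_subject_truth(gp$t1_curve, gp$t2_curve,
                                    gp$swap_decay, lags,
                                    seed = s_seed)
      truth[[k]] <- cbind(data.frame(subject_id = sid, group = g), tru)
      trials[[k]] <- generate_trials(tru, protocol,
                                     seed = split_seed(s_seed, 999L),
                                     subject_id = sid, group = g)
    }
  }
  trials <- do.call(rbind, trials)
  truth <- do.call(rbind, truth)
  rownames(trials) <- rownames(truth) <- NULL
  manifest <- list(
    seed = as.integer(seed),
    groups = groups,
    n_per_group = protocol$n_per_group,
    toas_ms = protocol$toas_ms,
    soa_by_group = as.list(protocol$soa_by_group),
    trials_per_toa = protocol$trials_per_toa,
    dual_target_fraction = protocol$dual_target_fraction,
    n_trials = nrow(trials)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(trials = trials, truth = truth, manifest = manifest)
}

#' Synthetic clinical (PANSS) scores tied to decay rates
#'
#' Generates synthetic PANSS subscale scores for a patient cohort in which
#' the positive, general and total scores correlate with the supplied
#' temporal decay rates (emulating the reported clinical association) and
#' the negative subscale does not. Purely synthetic plumbing so the
#' clinical-correlation stage runs end to end; scale means and spreads
#' mirror published patient summary tables.
#'
#' @param decay_rates data frame with `subject_id` and `decay_rate`.
#' @param seed integer seed.
#' @param r_target target correlation between decay rate and the positive
#'   subscale; default 0.6.
#' @return data frame with `subject_id`, `panss_positive`,
#'   `panss_negative`, `panss_general`, `panss_supplement`, `panss_total`.
#' @export
simulate_clinical_scores <- function(decay_rates, seed, r_target = 0.6) {
  stopifnot(all(c("subject_id", "decay_rate") %in% names(decay_rates)))
  d <- decay_rates[!is.na(decay_rates$decay_rate), ]
  n <- nrow(d)
  z <- as.numeric(scale(d$decay_rate))
  with_seed(seed, {
    mix <- function(sd_scale) {
      r_target * z + sqrt(1 - r_target^2) * stats::rnorm(n) * sd_scale
    }
    pos <- pmax(7, round(8.8 + 3.1 * mix(1)))
    gen <- pmax(16, round(20.7 + 3.7 * mix(1)))
    neg <- pmax(7, round(8.2 + 2.3 * stats::rnorm(n)))
    sup <- pmax(2, round(3.25 + 0.9 * stats::rnorm(n)))
    data.frame(subject_id = d$subject_id,
               panss_positive = pos, panss_negative = neg,
               panss_general = gen, panss_supplement = sup,
               panss_total = pos + neg + gen + sup)
  })
}
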