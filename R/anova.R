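#' Two-way mixed-design ANOVA (between: group, within: lag)
#'
#' Classical univariate split-plot ANOVA with one between-subject factor
#' (`group`) and one within-subject factor (`lag`), fitted with
#' [stats::aov()] using subject error strata. No sphericity correction is
#' applied, so for `n1 + n2` subjects and `k` lags the degrees of freedom
#' are `(1, n1+n2-2)` for group and `(k-1, (n1+n2-2)(k-1))` for lag and the
#' interaction. The design must be complete: every subject observed at
#' every lag.
#'
#' @param data long-format data frame with columns `subject_id`, `group`,
#'   `lag` and the measure column.
#' @param measure name of the response column; default `"value"`.
#' @return data frame of class `anova_table` with columns `effect`
#'   (`"group"`, `"lag"`, `"group:lag"`), `F`, `df_num`, `df_den`, `p`.
#'   Effects whose error mean square is zero (fully deterministic toy
#'   fixtures) are reported as `F = 0`, `p = 1`.
#' @export
mixed_anova <- function(data, measure = "value") {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "group", "lag", measure) %in% names(data)))
  d <- data.frame(
    subject_id = factor(data$subject_id),
    group = factor(data$group),
    lag = factor(data$lag),
    y = as.numeric(data[[measure]])
  )
  counts <- table(d$subject_id, d$lag)
  if (any(counts == 0L)) {
    bad <- which(counts == 0L, arr.ind = TRUE)[1L, ]
    stop("missing cell: subject ", rownames(counts)[bad[1]],
         " has no observation at lag ", colnames(counts)[bad[2]],
         call. = FALSE)
  }
  if (any(counts > 1L)) {
    stop("more than one observation per subject x lag cell; ",
         "aggregate first", call. = FALSE)
  }

  fit <- stats::aov(y ~ group * lag + Error(subject_id), data = d)
  s_between <- summary(fit)[["Error: subject_id"]][[1L]]
  s_within <- summary(fit)[["Error: Within"]][[1L]]

  pull <- function(smry, term) {
    i <- match(term, trimws(rownames(smry)))
    j <- match("Residuals", trimws(rownames(smry)))
    ss_e <- smry[j, "Sum Sq"]; df_e <- smry[j, "Df"]
    ss_t <- smry[i, "Sum Sq"]; df_t <- smry[i, "Df"]
    ms_e <- ss_e / df_e
    ms_t <- ss_t / df_t
    tol <- 1e-14 * max(1, abs(ss_t) + abs(ss_e))
    if (ms_e < tol) {
      if (ms_t < tol) {
        f <- 0; p <- 1
      } else {
        f <- Inf; p <- 0
      }
    } else {
      f <- ms_t / ms_e
      p <- stats::pf(f, df_t, df_e, lower.tail = FALSE)
    }
    data.frame(effect = term, F = f, df_num = df_t, df_den = df_e, p = p)
  }

  out <- rbind(pull(s_between, "group"),
               pull(s_within, "lag"),
               pull(s_within, "group:lag"))
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Mixed ANOVA (between: group, within: lag)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s F(%d,%d) = %.4g, p = %.4g\n",
                x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$p[i]))
  }
  invisible(x)
}

pooled_t_raw <- function(x1, x2) {
  # second sample minus first, pooled (Student) variance
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
    # degenerate deterministic fixtures: t = 0 when means agree
    if (mean(x1) == mean(x2)) {
      return(data.frame(t = 0, df = length(x1) + length(x2) - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(x2, x1, var.equal = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Per-lag simple-effect t tests between groups
#'
#' Independent two-sample pooled-variance t test at each lag, comparing the
#' two groups on the chosen measure; sign is second group level minus
#' first. No multiple-testing correction by default; `holm = TRUE` adds a
#' Holm-adjusted p column.
#'
#' @inheritParams mixed_anova
#' @param alpha significance level used for the `significant` flag.
#' @param holm apply Holm correction across lags?
#' @return data frame with columns `lag`, `t`, `df`, `p` (and `p_holm` if
#'   requested), `significant`.
#' @export
simple_effects <- function(data, measure = "value", alpha = 0.05,
                           holm = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("group", "lag", measure) %in% names(data)))
  g <- factor(data$group)
  if (nlevels(g) != 2L) stop("exactly two groups required", call. = FALSE)
  lags <- sort(unique(data$lag))
  out <- do.call(rbind, lapply(lags, function(l) {
    idx <- data$lag == l
    y <- as.numeric(data[[measure]][idx])
    gi <- g[idx]
    res <- pooled_t_raw(y[gi == levels(g)[1]], y[gi == levels(g)[2]])
    cbind(data.frame(lag = l), res)
  }))
  if (holm) {
    out$p_holm <- stats::p.adjust(out$p, method = "holm")
    out$significant <- out$p_holm < alpha
  } else {
    out$significant <- out$p < alpha
  }
  rownames(out) <- NULL
  out
}

#' Baseline-match check at a single lag
#'
#' Tests whether the two groups differ in T1 accuracy at a long lag where
#' accuracy has returned to baseline (the design check that presentation-
#' rate titration equalised basic perception). Independent two-sample
#' pooled-variance t with `df = n1 + n2 - 2`.
#'
#' @param curves data frame of per-subject curves with columns
#'   `subject_id`, `group`, `lag` and the measure column.
#' @param baseline_lag the lag (TOA / 100 ms) at which to compare.
#' @param measure response column, default `"pr_t1"`.
#' @return one-row data frame with `t`, `df`, `p`.
#' @export
baseline_match_test <- function(curves, baseline_lag, measure = "pr_t1") {
  stopifnot(all(c("subject_id", "group", "lag", measure) %in% names(curves)))
  idx <- curves$lag == baseline_lag
  if (!any(idx)) {
    stop("no observations at lag ", baseline_lag, call. = FALSE)
  }
  g <- factor(curves$group[idx])
  sub <- curves[idx, ]
  missing_subj <- setdiff(unique(curves$subject_id), sub$subject_id)
  if (length(missing_subj) > 0L) {
    stop("subjects lack the baseline lag: ",
         paste(utils::head(missing_subj, 3L), collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(sub[[measure]])
  pooled_t_raw(y[g == levels(g)[1]], y[g == levels(g)[2]])
}
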