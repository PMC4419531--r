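#' Logistic and exponential decay laws for temporal-order (swap) errors
#'
#' The probability of reporting both targets in reversed order decays with
#' lag `x` (TOA / 100 ms) towards a baseline `b`:
#' \itemize{
#'   \item EDF (exponential): `Pr(x) = b + exp(-a * x)`
#'   \item LDF (logistic):    `Pr(x) = b + 1 / (1 + exp(a * x))`
#' }
#' `a > 0` is the decay rate. Both laws have two parameters, hence equal
#' complexity, and both tend to `b` as `x` grows; at `x = 0` the EDF
#' anchors at `b + 1` and the LDF at `b + 0.5`.
#'
#' @param kind `"EDF"` or `"LDF"`.
#' @param decay_rate decay rate `a`, strictly positive.
#' @param baseline asymptotic swap probability `b` in `[0, 1)`.
#' @param x lag value(s), positive.
#' @return numeric vector of swap probabilities.
#' @examples
#' decay_value("EDF", 1.3, 0.03, x = 1) # about 0.3025
#' @export
decay_value <- function(kind = c("EDF", "LDF"), decay_rate, baseline, x) {
  kind <- match.arg(kind)
  stopifnot(decay_rate > 0, baseline >= 0, baseline < 1, all(x > 0))
  if (kind == "EDF") baseline + exp(-decay_rate * x)
  else baseline + 1 / (1 + exp(decay_rate * x))
}

#' Fit a decay law to a swap-rate curve
#'
#' Nonlinear least squares over `(decay_rate, baseline)` minimising the
#' mean squared error across lags, with multistart over decay-rate
#' initialisations `{0.5, 1, 1.5, 2, 3}` to escape local minima. Bounds:
#' `decay_rate` in `(0, 10]`, `baseline` in `[0, 0.5]` (swap baselines
#' above one half are behaviourally meaningless).
#'
#' @param swap_curve data frame with columns `lag` and `value` (observed
#'   swap probability per lag), at least 3 rows.
#' @param kind `"EDF"` or `"LDF"`.
#' @return list of class `decay_fit`: `kind`, `decay_rate`, `baseline`,
#'   `mse`, `lags` (the lags used), `n_lags`.
#' @export
fit_decay <- function(swap_curve, kind = c("EDF", "LDF")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(swap_curve),
            all(c("lag", "value") %in% names(swap_curve)))
  if (nrow(swap_curve) < 3L) {
    stop("need at least 3 lag points to fit a decay law", call. = FALSE)
  }
  x <- swap_curve$lag
  y <- swap_curve$value
  resid_fun <- function(p) y - decay_value(kind, p[1], min(p[2], 0.5), x)

  starts <- expand.grid(a = c(0.5, 1, 1.5, 2, 3),
                        b = c(0.02, max(0, min(0.45, min(y)))))
  best <- NULL
  msgs <- character()
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(a = starts$a[i], b = starts$b[i]),
        lower = c(1e-6, 0), upper = c(10, 0.5), fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 1024L,
                                             ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      msgs <- c(msgs, conditionMessage(fit))
      next
    }
    if (fit$info %in% c(0L, 9L)) {
      msgs <- c(msgs, fit$message)
      next
    }
    sse <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse)
    }
  }
  if (is.null(best)) {
    stop("decay fit failed from every start: ",
         paste(unique(msgs), collapse = "; "), call. = FALSE)
  }
  structure(list(kind = kind,
                 decay_rate = unname(best$par[1]),
                 baseline = unname(best$par[2]),
                 mse = best$sse / length(y),
                 lags = x, n_lags = length(y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%s fit: decay rate = %.4g, baseline = %.4g, MSE = %.3g (%d lags)\n",
              x$kind, x$decay_rate, x$baseline, x$mse, x$n_lags))
  invisible(x)
}

#' Fit both decay laws per group and pick the winner by MSE
#'
#' Fits the EDF and the LDF to each group's mean swap curve and selects,
#' per group, the law with the smaller mean squared error. Both laws have
#' two parameters, so raw MSE comparison needs no flexibility correction.
#'
#' @param group_swap_curves named list of data frames (one per group), each
#'   with columns `lag` and `value`.
#' @return data frame with one row per group and law: `group`, `kind`,
#'   `decay_rate`, `baseline`, `mse`, `winner` (logical).
#' @export
compare_decay_models <- function(group_swap_curves) {
  stopifnot(is.list(group_swap_curves), length(group_swap_curves) >= 1L,
            !is.null(names(group_swap_curves)))
  rows <- lapply(names(group_swap_curves), function(g) {
    fits <- lapply(c("LDF", "EDF"), function(k)
      fit_decay(group_swap_curves[[g]], kind = k))
    mses <- vapply(fits, `[[`, numeric(1), "mse")
    do.call(rbind, lapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      data.frame(group = g, kind = f$kind, decay_rate = f$decay_rate,
                 baseline = f$baseline, mse = f$mse,
                 winner = f$mse == min(mses))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject decay rates from swap curves
#'
#' Fits the chosen decay law to every subject's swap-probability curve.
#' Subjects whose fit fails (e.g. all-zero swaps, for which the decay rate
#' is unidentifiable) are reported as `NA` with a warning rather than
#' aborting the batch.
#'
#' @param curves data frame with columns `subject_id`, `lag`, `pr_swap`.
#' @param kind decay law, default `"EDF"`.
#' @return data frame with columns `subject_id`, `decay_rate`, `baseline`,
#'   `mse` (`NA` where the fit failed).
#' @export
subject_decay_rates <- function(curves, kind = "EDF") {
  stopifnot(all(c("subject_id", "lag", "pr_swap") %in% names(curves)))
  ids <- unique(curves$subject_id)
  out <- do.call(rbind, lapply(ids, function(sid) {
    d <- curves[curves$subject_id == sid, ]
    curve <- data.frame(lag = d$lag, value = d$pr_swap)
    if (all(curve$value == 0)) {
      warning("subject ", sid, ": all-zero swap curve, decay rate ",
              "unidentifiable", call. = FALSE)
      return(data.frame(subject_id = sid, decay_rate = NA_real_,
                        baseline = NA_real_, mse = NA_real_))
    }
    fit <- tryCatch(fit_decay(curve, kind = kind), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("subject ", sid, ": ", conditionMessage(fit), call. = FALSE)
      return(data.frame(subject_id = sid, decay_rate = NA_real_,
                        baseline = NA_real_, mse = NA_real_))
    }
    data.frame(subject_id = sid, decay_rate = fit$decay_rate,
               baseline = fit$baseline, mse = fit$mse)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation between decay rates and a clinical variable
#'
#' Linear (Pearson) correlation between per-subject decay rates and a
#' clinical score, with `df = n - 2` and a two-tailed p value from the t
#' transform `t = r * sqrt(df / (1 - r^2))`. Pairs with a missing value on
#' either side are dropped.
#'
#' @param rates data frame from [subject_decay_rates()].
#' @param clinical data frame with `subject_id` and clinical score columns.
#' @param variable name of the clinical column to correlate.
#' @return one-row data frame with `variable`, `r`, `df`, `p`, `n`.
#' @export
correlate_decay_with_clinical <- function(rates, clinical, variable) {
  stopifnot(all(c("subject_id", "decay_rate") %in% names(rates)),
            "subject_id" %in% names(clinical),
            variable %in% names(clinical))
  m <- merge(rates[, c("subject_id", "decay_rate")],
             clinical[, c("subject_id", variable)], by = "subject_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 4L) {
    stop("need at least 4 complete pairs, got ", nrow(m), call. = FALSE)
  }
  x <- m$decay_rate
  y <- as.numeric(m[[variable]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in ",
         if (stats::sd(x) == 0) "decay rates" else variable, call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(variable = variable, r = unname(ct$estimate),
             df = unname(ct$parameter), p = ct$p.value, n = nrow(m))
}
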