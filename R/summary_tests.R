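#' Pooled-variance two-sample t test from summary statistics
#'
#' Computes the Student (pooled-variance) two-sample t statistic from
#' group means, standard deviations and sizes, as needed to recompute the
#' t columns of published demographic tables. Sign convention: second
#' group minus first, `t = (m2 - m1) / (sp * sqrt(1/n1 + 1/n2))`, with
#' `df = n1 + n2 - 2` and a two-tailed p value.
#'
#' @param mean1,sd1,n1 first group's mean, SD and size.
#' @param mean2,sd2,n2 second group's mean, SD and size.
#' @return one-row data frame with `t`, `df`, `p`.
#' @examples
#' t_from_summary(90.29, 21.86, 24, 104.50, 10.55, 24) # t about 2.87
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      return(data.frame(t = 0, df = df, p = 1))
    }
    stop("both SDs zero with unequal means: t is infinite", call. = FALSE)
  }
  tval <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  data.frame(t = tval, df = df,
             p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

#' Recompute a summary table's t column
#'
#' Batch wrapper over [t_from_summary()] for a table of per-variable group
#' summaries (the layout of published demographic/clinical tables). Rows
#' lacking a second group (e.g. symptom scales rated only in patients) are
#' passed through untested with `NA` statistics. Malformed rows are
#' reported and skipped, not fatal.
#'
#' @param summaries data frame with columns `variable`, `group1`, `mean1`,
#'   `sd1`, `n1`, `group2`, `mean2`, `sd2`, `n2` (extra columns are
#'   carried through).
#' @return the input with `t`, `df`, `p` and `tested` columns appended.
#' @export
reproduce_table <- function(summaries) {
  need <- c("variable", "group1", "mean1", "sd1", "n1",
            "group2", "mean2", "sd2", "n2")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0L) {
    stop("summary table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- summaries
  out$t <- rep(NA_real_, nrow(out))
  out$df <- rep(NA_real_, nrow(out))
  out$p <- rep(NA_real_, nrow(out))
  out$tested <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    if (is.na(r$mean2) || is.na(r$sd2) || is.na(r$n2) ||
        identical(r$group2, "") || is.na(r$group2)) {
      next # single-group row, passed through untested
    }
    res <- tryCatch(
      t_from_summary(r$mean1, r$sd1, r$n1, r$mean2, r$sd2, r$n2),
      error = function(e) {
        warning("row '", r$variable, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(res)) next
    out$t[i] <- res$t
    out$df[i] <- res$df
    out$p[i] <- res$p
    out$tested[i] <- TRUE
  }
  out
}

#' Read a group-summary CSV
#'
#' Reads a summary table in the documented layout (see
#' [reproduce_table()]), validating that the required header columns are
#' present and naming the first missing one otherwise. Extra columns (such
#' as a transcribed printed t value) are allowed and kept.
#'
#' @param path CSV file path.
#' @return data frame of summaries.
#' @export
read_summary_csv <- function(path) {
  need <- c("variable", "group1", "mean1", "sd1", "n1",
            "group2", "mean2", "sd2", "n2")
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  bad <- setdiff(need, header)
  if (length(bad) > 0L) {
    stop("summary CSV ", path, ": missing column '", bad[1], "'",
         call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
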