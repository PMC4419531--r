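#' Aggregate trial records into per-subject accuracy and swap curves
#'
#' Reduces trial-level RSVP records to each subject's per-lag curve.
#' Triple-target catch trials are excluded. Per subject and TOA, over dual
#' trials only:
#' \itemize{
#'   \item `pr_t1`: fraction of trials with T1 reported in any position
#'     (position-lenient scoring; `strict_position = TRUE` requires T1 in
#'     the first response slot when both targets are reported).
#'   \item `pr_t2_given_t1`: among T1-correct trials, fraction with T2
#'     also reported.
#'   \item `pr_swap`: fraction of all dual trials with both targets
#'     reported but T2 before T1.
#' }
#' Lags are expressed as TOA / 100 ms.
#'
#' @param trials data frame in the [generate_trials()] layout.
#' @param strict_position require targets in veridical response positions
#'   for T1 scoring? Default `FALSE`.
#' @return data frame with columns `subject_id`, `group`, `lag`, `pr_t1`,
#'   `pr_t2_given_t1`, `pr_swap`, `n_trials`.
#' @export
aggregate_trials <- function(trials, strict_position = FALSE) {
  need <- c("subject_id", "group", "condition", "toa_ms",
            "t1", "t2", "report_1", "report_2")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- trials[trials$condition == "dual", , drop = FALSE]
  if (nrow(d) == 0L) stop("no dual-target trials to aggregate",
                          call. = FALSE)
  rep_cols <- intersect(c("report_1", "report_2", "report_3"), names(d))
  reports <- as.matrix(d[, rep_cols, drop = FALSE])
  reports[is.na(reports)] <- ""

  pos1 <- pos_of_vec(reports, d$t1)
  pos2 <- pos_of_vec(reports, d$t2)

  # strict scoring: T1 must occupy the first response slot
  t1_ok <- if (strict_position) !is.na(pos1) & pos1 == 1L else !is.na(pos1)
  both <- !is.na(pos1) & !is.na(pos2)
  swapped <- both & pos2 < pos1

  # separator never present in subject ids or TOAs
  key <- factor(paste(d$subject_id, d$toa_ms, sep = "\x1f"))
  # complete-grid check: every subject must have every TOA
  grid <- table(d$subject_id, d$toa_ms)
  if (any(grid == 0L)) {
    bad <- which(grid == 0L, arr.ind = TRUE)[1L, ]
    stop("subject ", rownames(grid)[bad[1]], " has no dual trials at TOA ",
         colnames(grid)[bad[2]], " ms", call. = FALSE)
  }

  agg <- function(v) tapply(v, key, mean)
  n_tab <- tapply(rep(1, nrow(d)), key, sum)
  # t2 | t1: among t1-correct trials only
  t2_given <- vapply(levels(key), function(kk) {
    i <- key == kk
    denom <- sum(t1_ok[i])
    if (denom == 0L) return(NA_real_)
    sum(both[i] & t1_ok[i]) / denom
  }, numeric(1))

  keys <- strsplit(levels(key), "\x1f", fixed = TRUE)
  out <- data.frame(
    subject_id = vapply(keys, `[`, character(1), 1L),
    toa_ms = as.integer(vapply(keys, `[`, character(1), 2L)),
    pr_t1 = as.numeric(agg(t1_ok)),
    pr_t2_given_t1 = as.numeric(t2_given),
    pr_swap = as.numeric(agg(swapped)),
    n_trials = as.integer(n_tab)
  )
  gmap <- unique(d[, c("subject_id", "group")])
  out <- merge(out, gmap, by = "subject_id")
  out$lag <- out$toa_ms / 100
  out <- out[order(out$subject_id, out$lag),
             c("subject_id", "group", "lag", "pr_t1", "pr_t2_given_t1",
               "pr_swap", "n_trials")]
  rownames(out) <- NULL
  out
}

pos_of_vec <- function(reports, targets) {
  p <- rep(NA_integer_, nrow(reports))
  for (j in seq_len(ncol(reports))) {
    hit <- is.na(p) & reports[, j] == targets & reports[, j] != ""
    p[hit] <- j
  }
  p
}
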