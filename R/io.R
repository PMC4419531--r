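#' Read and write accuracy-by-lag curves
#'
#' Curves serialise to CSV with header `lag_100ms,value` and to JSON as
#' `{"lags": [...], "values": [...]}`. Readers validate the header/keys
#' and name the first offending column.
#'
#' @param curve data frame with columns `lag` and `value`.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return a curve
#'   data frame.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(all(c("lag", "value") %in% names(curve)))
  utils::write.csv(
    data.frame(lag_100ms = curve$lag, value = curve$value),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("lag_100ms", "value")
  bad <- setdiff(need, names(d))
  if (length(bad) > 0L) {
    stop("curve CSV ", path, ": missing column '", bad[1], "'",
         call. = FALSE)
  }
  data.frame(lag = d$lag_100ms, value = d$value)
}

#' @rdname curve_io
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(all(c("lag", "value") %in% names(curve)))
  jsonlite::write_json(list(lags = curve$lag, values = curve$value),
                       path, digits = NA)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(c("lags", "values"), names(d))
  if (length(bad) > 0L) {
    stop("curve JSON ", path, ": missing key '", bad[1], "'",
         call. = FALSE)
  }
  data.frame(lag = d$lags, value = d$values)
}

#' Serialise gamma AB parameters to and from JSON
#'
#' @param params a [gamma_ab_params()] object.
#' @param path file path.
#' @name params_io
NULL

#' @rdname params_io
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "gamma_ab_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname params_io
#' @export
read_params_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("shape", "scale", "baseline", "depth", "noise_halfwidth")
  bad <- setdiff(need, names(d))
  if (length(bad) > 0L) {
    stop("params JSON ", path, ": missing key '", bad[1], "'",
         call. = FALSE)
  }
  gamma_ab_params(d$shape, d$scale, d$baseline, d$depth,
                  d$noise_halfwidth)
}

#' Read a trial-record CSV
#'
#' Validates the documented trial header
#' `subject_id,group,trial_index,condition,toa_ms,t1,t2,t3,report_1,report_2,report_3`
#' and returns the trial table with report columns as character.
#'
#' @param path CSV file path.
#' @return trial data frame in the [generate_trials()] layout.
#' @export
read_trials_csv <- function(path) {
  need <- c("subject_id", "group", "trial_index", "condition", "toa_ms",
            "t1", "t2", "t3", "report_1", "report_2", "report_3")
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       colClasses = "character")
  bad <- setdiff(need, names(d))
  if (length(bad) > 0L) {
    stop("trial CSV ", path, ": missing column '", bad[1], "'",
         call. = FALSE)
  }
  d$trial_index <- as.integer(d$trial_index)
  d$toa_ms <- as.integer(d$toa_ms)
  for (cc in c("t3", "report_1", "report_2", "report_3")) {
    d[[cc]][is.na(d[[cc]])] <- ""
  }
  d
}
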