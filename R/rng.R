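#' Evaluate an expression under a fixed RNG seed, restoring global state
#'
#' All stochastic operations in blinkstat are pure functions of their
#' arguments and a seed. This helper runs `expr` with the RNG seeded to
#' `seed` and puts the caller's RNG state back afterwards, so library calls
#' never perturb a user's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-unit seed from a master seed
#'
#' Splitting rule used for per-subject (and per-replicate) random streams:
#' `child = (master * 48271 + index) mod (2^31 - 1)`. The multiplier is the
#' classic MINSTD LCG constant; the point is not cryptographic quality but
#' that child streams are decorrelated and that adding subjects or
#' replicates never perturbs the streams of existing ones.
#'
#' @param master master integer seed.
#' @param index positive integer index of the child stream.
#' @return single integer seed below 2^31.
#' @keywords internal
split_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1
  as.integer((as.numeric(master) %% m * 48271 + as.numeric(index)) %% m)
}
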