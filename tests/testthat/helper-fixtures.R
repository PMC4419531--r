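# Shared fixtures: the published control-group curve parameters and small
# synthetic designs used across test files.

ctrl_params <- function(noise = 0.4) {
  gamma_ab_params(2.1, 0.96, 0.86, 0.87, noise_halfwidth = noise)
}

paper_lags <- 1:8

# deterministic long-format toy design: 2 groups x n subjects x k lags
toy_design <- function(n_per_group = 2, lags = c(1, 2), values) {
  d <- expand.grid(
    subject = seq_len(2 * n_per_group), lag = lags,
    KEEP.OUT.ATTRS = FALSE
  )
  d$subject_id <- sprintf("s%02d", d$subject)
  d$group <- ifelse(d$subject <= n_per_group, "g1", "g2")
  d <- d[order(d$subject, d$lag), c("subject_id", "group", "lag")]
  rownames(d) <- NULL
  d$value <- values
  d
}

# independently coded pooled-variance two-sample t (second minus first)
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  t <- (mean(x2) - mean(x1)) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}
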