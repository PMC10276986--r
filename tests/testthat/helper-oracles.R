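# Independent oracles used across the suite.

# Brute-force step-up: explicit scan of every threshold i * alpha / m.
bf_stepup_k <- function(p, alpha) {
  ps <- sort(p)
  m <- length(p)
  k <- 0L
  for (i in seq_len(m)) {
    if (ps[i] <= i * alpha / m) k <- i
  }
  k
}

# Direct evaluation of the weight formula, no log-space tricks.
direct_weights <- function(x, a) {
  length(x) * x^(-a) / sum(x^(-a))
}

# p-value mixture with known signal labels: n1 strong signals among m.
signal_mixture <- function(m, n1, strength = 1e-4) {
  is_signal <- c(rep(TRUE, n1), rep(FALSE, m - n1))
  p <- runif(m)
  p[is_signal] <- p[is_signal] * strength
  list(p = p, is_signal = is_signal)
}

# identity resampling hook for bagging_optimize
identity_resample <- function(k, m, size) seq_len(m)
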