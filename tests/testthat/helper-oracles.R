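# Independent oracles and small builders used across the suite.

# noiseless constant-speed trajectory sampled every dt until len is covered
make_noiseless_traj <- function(v, len, dt = 0.2, channel = "color1",
                                id = 1L) {
  k <- floor(len / (v * dt) + 1e-9)
  tt <- seq(0, k) * dt
  data.frame(complex_id = id, channel = channel,
             frame = seq_along(tt) - 1L, time_s = tt, position_um = v * tt,
             stringsAsFactors = FALSE)
}

# mean of a zero-truncated Gaussian, closed form
truncnorm_mean <- function(mu, sigma) {
  a <- -mu / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}

# permutation two-sample test using the Welch t statistic
perm_ttest_p <- function(a, b, n_perm = 1e4) {
  welch_t <- function(x, y) {
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  obs <- abs(welch_t(a, b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(welch_t(pool[idx], pool[-idx])) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# enumeration oracle for the dual-color probability of a two-copy complex:
# sum over ordered color pairs whose two draws differ
dual_prob_enumerated <- function(r) {
  g <- 1 - r
  pairs <- expand.grid(first = c("c1", "c2"), second = c("c1", "c2"))
  p <- c(c1 = r, c2 = g)
  sum(apply(pairs, 1, function(pr) {
    if (pr["first"] != pr["second"]) p[[pr["first"]]] * p[[pr["second"]]] else 0
  }))
}

# 3-sigma binomial band for an observed fraction
binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
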