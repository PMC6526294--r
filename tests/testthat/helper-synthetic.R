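# shared fixtures, all generated in code

# exact mono-exponential samples on the standard draw schedule
exact_decay_samples <- function(c0 = 8, k = 0.25,
                                t_s = c(120, 165, 210, 255, 300)) {
  list(t_s = t_s, conc = c0 * exp(-(k / 60) * t_s))
}

# a noise-free participant: instantaneous mixing, no plate noise, no jitter
noise_free_participant <- function(seed = 7) {
  simulate_participant(seed = seed, mixing_tau_s = 0,
                       absorbance_noise_sd = 0, timing_jitter_sd = 0)
}

# closed-form OLS via the normal equations, the independent fitting oracle
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  c(intercept = (sum(y) - slope * sum(x)) / n, slope = slope)
}

# rank-then-Pearson Spearman oracle (mid-ranks for ties)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  mx <- rx - mean(rx); my <- ry - mean(ry)
  sum(mx * my) / sqrt(sum(mx^2) * sum(my^2))
}
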