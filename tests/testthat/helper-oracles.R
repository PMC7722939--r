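# Independent oracles used across tests; none of these call the package's
# own implementation of the quantity they check.

# Textbook equal-N, equal-variance unpaired t statistic with per-group
# variance v (independent route for the r = 0 case of the design t).
unpaired_t_textbook <- function(mu1, mu2, v, N) {
  (mu1 - mu2) / sqrt(v / N + v / N)
}

# Exact gamma-function c4 (the series in the package approximates this).
c4_exact <- function(N) {
  sqrt(2 / (N - 1)) * exp(lgamma(N / 2) - lgamma((N - 1) / 2))
}

# Brute-force Monte Carlo oracle for the expected design t statistic at a
# single trial count: simulates replicate population pairs from the same
# lognormal hierarchy, averages per-replicate means and c4-corrected SDs of
# the subject-level differences, and blocks replicates to attach a standard
# error. Written directly against stats::rlnorm / rnorm, not the package
# generators.
mc_t_oracle <- function(mu1, mu2, sigma_s, sigma_t, r, N, n,
                        reps = 10000, blocks = 20, seed = 1) {
  set.seed(seed)
  ln_par <- function(m, s) {
    list(mu = log(m^2 / sqrt(m^2 + s^2)), sig = sqrt(log(1 + s^2 / m^2)))
  }
  p1 <- ln_par(mu1, sigma_s)
  p2 <- ln_par(mu2, sigma_s)
  log_cov <- log(1 + r * sigma_s^2 / (mu1 * mu2))
  rho <- log_cov / (p1$sig * p2$sig)
  c4N <- c4_exact(N)
  per_block <- reps / blocks
  stats <- replicate(blocks, {
    dm <- numeric(per_block)
    ds <- numeric(per_block)
    for (k in seq_len(per_block)) {
      u1 <- rnorm(N)
      u2 <- rnorm(N)
      m1 <- exp(p1$mu + p1$sig * u1)
      m2 <- exp(p2$mu + p2$sig * (rho * u1 + sqrt(1 - rho^2) * u2))
      x1 <- vapply(m1, function(m) {
        mean(rlnorm(n, log(m^2 / sqrt(m^2 + sigma_t^2)),
                    sqrt(log(1 + sigma_t^2 / m^2))))
      }, numeric(1))
      x2 <- vapply(m2, function(m) {
        mean(rlnorm(n, log(m^2 / sqrt(m^2 + sigma_t^2)),
                    sqrt(log(1 + sigma_t^2 / m^2))))
      }, numeric(1))
      d <- x1 - x2
      dm[k] <- mean(d)
      ds[k] <- sd(d) / c4N
    }
    mean(dm) / (mean(ds) / sqrt(N))
  })
  list(t = mean(stats), sem = sd(stats) / sqrt(blocks))
}

# Assembles a single trial stream per subject whose first `block` trials come
# from measure 1 and next `block` from measure 2 of a paired fixture, so the
# split-half correlation probes the asymptotic between-measure correlation.
paired_stream <- function(N, block, mu1, mu2, sigma_s, sigma_t, r, seed) {
  fx <- generate_paired_fixture(N, block, mu1, mu2, sigma_s, sigma_t, r,
                                seed = seed)
  fx$trial_index <- fx$trial_index + (fx$measure - 1L) * block
  fx[order(fx$subject_id, fx$trial_index),
     c("subject_id", "trial_index", "amplitude_mv")]
}
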