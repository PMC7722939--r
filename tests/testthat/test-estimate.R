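make_tidy <- function(mat) {
  # rows = subjects, cols = trials
  tibble::tibble(
    subject_id = rep(sprintf("S%02d", seq_len(nrow(mat))), each = ncol(mat)),
    trial_index = rep(seq_len(ncol(mat)), times = nrow(mat)),
    amplitude_mv = as.vector(t(mat))
  )
}

test_that("per-subject summaries match hand arithmetic", {
  d <- tibble::tibble(subject_id = c("a", "a", "b", "b", "b"),
                      trial_index = c(1, 2, 1, 2, 3),
                      amplitude_mv = c(1, 2, 3, 3, 3))
  s <- summarize_subjects(d)
  expect_equal(s$mean_mv, c(1.5, 3))
  expect_equal(s$sd_mv[1], 0.7071068, tolerance = 1e-6)
  expect_equal(s$cv[1], 0.4714045, tolerance = 1e-6)
  expect_equal(s$cv[2], 0) # constant-amplitude subject
  expect_true(is.na(s$skewness[1])) # undefined below 3 trials
  expect_equal(s$n_trials, c(2L, 3L))
})

test_that("subjects with fewer than two trials are rejected by name", {
  d <- tibble::tibble(subject_id = c("ok", "ok", "lone"),
                      trial_index = c(1, 2, 1),
                      amplitude_mv = c(1, 2, 1))
  expect_error(summarize_subjects(d), "lone",
               class = "mepplan_domain_error")
  expect_error(estimate_population(d), class = "mepplan_domain_error")
})

test_that("per-subject CV recovers the generating trial variability", {
  fx <- generate_fixture(1, 1e4, 1, 0, 0.5, seed = 23)
  s <- summarize_subjects(fx)
  # SE of a CV estimate from n trials is roughly cv * sqrt(1/(2n) + cv^2/n)
  se <- 0.5 * sqrt(1 / (2e4) + 0.25 / 1e4)
  expect_lt(abs(s$cv - 0.5), 3 * se)
})

test_that("population estimates decompose variance and reduce on rectangles", {
  mat <- rbind(c(1, 2, 3, 4), c(4, 4, 6, 6), c(8, 8, 8, 12))
  est <- estimate_population(make_tidy(mat))
  means <- rowMeans(mat)
  vars <- apply(mat, 1, var)
  expect_equal(est$mu_subjects, mean(means))
  expect_equal(est$sigma_subjects_obs, sd(means))
  # rectangular: pooled variance is the plain mean of per-subject variances
  expect_equal(est$sigma_trials, sqrt(mean(vars)))
  expect_equal(est$n, 4)
  expect_equal(est$cv_trials_range, range(sqrt(vars) / means))
  expect_false(est$degenerate)
})

test_that("degenerate decompositions report a zero asymptotic SD with a warning", {
  # identical subject means, large within-subject spread
  mat <- rbind(c(0.5, 1.5), c(0.6, 1.4), c(0.4, 1.6))
  expect_warning(est <- estimate_population(make_tidy(mat)),
                 "trial noise")
  expect_identical(est$sigma_subjects, 0)
  expect_true(est$degenerate)
  # all-constant data is not flagged: there is simply no variance anywhere
  flat <- make_tidy(matrix(2, 3, 4))
  est0 <- estimate_population(flat)
  expect_identical(est0$sigma_subjects_obs, 0)
  expect_identical(est0$sigma_trials, 0)
})

test_that("population parameters are recovered across twenty fixture seeds", {
  truth <- c(mu = 1.48, sigma_s = 0.57, sigma_t = 1.01)
  ests <- t(vapply(1:20, function(s) {
    g <- glance(estimate_population(
      generate_fixture(500, 100, 1.48, 0.57, 1.01, seed = s)))
    c(g$mu_subjects, g$sigma_subjects, g$sigma_trials)
  }, numeric(3)))
  sem <- apply(ests, 2, sd) / sqrt(20)
  expect_true(all(abs(colMeans(ests) - truth) < 3 * sem))
})

test_that("split-half correlation handles the exact and null cases", {
  # second half duplicates the first: r = 1
  half <- matrix(rlnorm(5 * 10), 5, 10)
  dup <- make_tidy(cbind(half, half))
  sh <- split_half_r(dup, block = 10)
  expect_equal(sh$r, 1)
  expect_identical(sh$N, 5L)
  expect_identical(nrow(tidy(sh)), 5L)
  # guards
  expect_error(split_half_r(dup, block = 11), class = "mepplan_domain_error")
  two <- make_tidy(matrix(rlnorm(2 * 20), 2, 20))
  expect_error(split_half_r(two, block = 10), class = "mepplan_domain_error")
})

test_that("split-half correlation on independent halves is null", {
  set.seed(71)
  # two independent latent means per subject: asymptotic r = 0
  stream <- paired_stream(500, 20, 1, 1, 0.5, 0.5, r = 0, seed = 71)
  sh <- split_half_r(stream, block = 20)
  expect_lt(abs(sh$r), 3 / sqrt(500))
})

test_that("split-half correlation follows the attenuation law across block sizes", {
  for (b in c(5, 10, 20)) {
    obs <- vapply(1:8, function(s) {
      split_half_r(paired_stream(500, b, 1.0, 1.0, 0.5, 0.5, r = 0.9,
                                 seed = 100 + s), block = b)$r
    }, numeric(1))
    pred <- reliability_at_n(0.9, 0.5, 0.5, b)
    sem <- sd(obs) / sqrt(8)
    expect_lt(abs(mean(obs) - pred), 3 * sem + 0.005)
  }
})

test_that("split-half estimates match the attenuation prediction at block 20", {
  obs <- vapply(1:20, function(s) {
    split_half_r(paired_stream(500, 20, 1.0, 1.0, 0.5, 0.5, r = 0.9,
                               seed = 200 + s), block = 20)$r
  }, numeric(1))
  pred <- reliability_at_n(0.9, 0.5, 0.5, 20) # = 0.857 by hand
  expect_equal(pred, 0.9 * 0.25 / (0.25 + 0.25 / 20))
  sem <- sd(obs) / sqrt(20)
  expect_lt(abs(mean(obs) - pred), 3 * sem)
})

test_that("planning reports reproduce the published worked plans", {
  # estimate object carrying the published Experiment-1-style parameters
  est <- structure(
    list(N = 20L, n = 100, mu_subjects = 1.48, sigma_subjects_obs = 0.5772,
         sigma_subjects = 0.57, sigma_trials = 1.01, cv_subjects = 0.39,
         cv_trials_mean = 0.61, cv_trials_range = c(0.29, 0.87),
         degenerate = FALSE, subjects = NULL),
    class = "mep_population_estimate"
  )
  rep <- planning_report(est, eta = 0.1, p_incl = 0.95, z_sum = 2.80,
                         delta_means = c(1.23, 0.62), r = 0.61,
                         n_grid = c(5, 10, 20, 30, 100, Inf))
  expect_equal(rep$single_subject$n_opt[rep$single_subject$which == "mean"],
               143)
  expect_equal(sort(rep$single_subject$n_opt), c(33, 143, 291))
  # population error table (percent, one decimal)
  pe <- rep$population_error
  expect_equal(pe$eta_percent[pe$n == 10], 19.3)
  expect_equal(pe$eta_percent[pe$n == 30], 17.7)
  expect_equal(pe$eta_percent[!is.finite(pe$n)], 16.9)
  # subjects needed at 10 trials: 10 within, 18 between
  ss <- rep$sample_size
  expect_equal(ss$N_within[ss$n == 10], 10)
  expect_equal(ss$N_between[ss$n == 10], 18)
  expect_equal(ss$N_within[ss$n == 30], 7)
  expect_equal(ss$N_within[!is.finite(ss$n)], 6)
  # paired table requires the correlation
  expect_error(planning_report(est, delta_means = c(1.23, 0.62)),
               class = "mepplan_domain_error")
})

test_that("planning reports degrade gracefully with zero variability", {
  flat <- make_tidy(matrix(2, 3, 4))
  rep <- planning_report(estimate_population(flat))
  expect_true(all(rep$single_subject$n_opt == 0))
  expect_true(all(rep$population_error$eta == 0))
})

test_that("conservative difference construction halves the lower confidence limit", {
  est <- structure(
    list(N = 20L, n = 100, mu_subjects = 1.48, sigma_subjects_obs = 0.5772,
         sigma_subjects = 0.57, sigma_trials = 1.01, cv_subjects = 0.39,
         cv_trials_mean = 0.61, cv_trials_range = c(0.29, 0.87),
         degenerate = FALSE, subjects = NULL),
    class = "mep_population_estimate"
  )
  rep <- planning_report(est, conservative = TRUE, r = 0.61, z_sum = 2.80)
  mu1 <- rep$params$delta_means[1]
  expect_equal(mu1, 1.48 * (1 - error_population(20, 0.39)))
  expect_equal(rep$params$delta_means[2], mu1 / 2)
  expect_equal(mu1, 1.23, tolerance = 3e-3)
})

test_that("tidy and glance methods expose the fitted quantities", {
  fx <- generate_fixture(10, 30, 1, 0.5, 0.5, seed = 4)
  est <- estimate_population(fx)
  td <- tidy(est)
  expect_identical(td$estimate[td$parameter == "mu_subjects"],
                   est$mu_subjects)
  g <- glance(est)
  expect_identical(g$N, 10L)
  sh <- split_half_r(fx, 15)
  expect_identical(glance(sh)$r, sh$r)
})
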