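# Monte Carlo validation engine: lognormal single-subject, hierarchical
# population and correlated-pair generators, with empirical error-percentile
# and t curves to compare against the analytic planning relations.

# Cumulative row means of a matrix (rows = replicates, cols = trials).
row_cummean <- function(m) {
  out <- m
  nc <- ncol(m)
  if (nc > 1) {
    for (j in 2:nc) out[, j] <- out[, j - 1] + m[, j]
  }
  sweep(out, 2, seq_len(nc), "/")
}

new_error_curve <- function(n, eta, kind, params) {
  structure(
    tibble::tibble(n = n, eta = eta),
    class = c("mep_error_curve", class(tibble::tibble())),
    kind = kind, params = params
  )
}

#' Simulated single-subject error-percentile curve
#'
#' Draws `reps` simulated subjects, each with `n_max` i.i.d. lognormal trials
#' (arithmetic mean `mu`, SD `cv * mu`), computes each subject's cumulative
#' average, and returns for every `n` the `percentile` of the absolute
#' relative error of the cumulative average with respect to the true mean.
#' With `percentile = 0.95` the curve estimates the relative error at 95%
#' inclusion probability and is directly comparable to [error_single()].
#'
#' @param cv Within-subject coefficient of variation (>= 0).
#' @param n_max Trials per simulated subject.
#' @param reps Number of simulated subjects.
#' @param percentile Probability level of the error percentile.
#' @param mu True mean amplitude (mV); errors are expressed relative to it.
#' @param seed Integer seed; identical seeds give identical curves.
#' @return A tibble of class `"mep_error_curve"` with columns `n`, `eta`.
#' @examples
#' simulate_single_subject_curve(0.5, n_max = 50, reps = 500, seed = 1)
#' @export
simulate_single_subject_curve <- function(cv, n_max = 100, reps = 10000,
                                          percentile = 0.95, mu = 1,
                                          seed = 1) {
  check_nonneg(cv, "cv")
  check_pos(mu, "mu")
  check_prob(percentile, "percentile")
  set.seed(seed)
  trials <- matrix(rlnorm_matched(reps * n_max, mu, cv * mu),
                   nrow = reps, ncol = n_max)
  err <- abs(row_cummean(trials) - mu) / mu
  eta <- apply(err, 2, quantile, probs = percentile, names = FALSE)
  new_error_curve(seq_len(n_max), eta, "single_subject",
                  list(cv = cv, mu = mu, reps = reps,
                       percentile = percentile, seed = seed))
}

#' Simulated population-mean error-percentile curve
#'
#' Draws `reps` populations of `N` subjects. Each subject's true mean is
#' lognormal (`mu_subjects`, `sigma_subjects`); each subject contributes
#' `n_max` lognormal trials around its own mean with SD `sigma_trials`. The
#' cumulative population mean (average over subjects of cumulative subject
#' means) is compared to `mu_subjects`, and the stated percentile of the
#' absolute relative error across replicate populations is returned per `n`,
#' comparable to [error_population_n()].
#'
#' @param mu_subjects,sigma_subjects,sigma_trials Population parameters (mV).
#' @param N Subjects per population.
#' @inheritParams simulate_single_subject_curve
#' @return A tibble of class `"mep_error_curve"` with columns `n`, `eta`.
#' @export
simulate_population_curve <- function(mu_subjects, sigma_subjects,
                                      sigma_trials, N, n_max = 100,
                                      reps = 10000, percentile = 0.95,
                                      seed = 1) {
  check_pos(mu_subjects, "mu_subjects")
  check_nonneg(sigma_subjects, "sigma_subjects")
  check_nonneg(sigma_trials, "sigma_trials")
  check_count(N, "N")
  check_prob(percentile, "percentile")
  set.seed(seed)
  n_rows <- reps * N
  subject_means <- rlnorm_matched(n_rows, mu_subjects, sigma_subjects)
  trials <- matrix(rlnorm_matched(n_rows * n_max, subject_means, sigma_trials),
                   nrow = n_rows, ncol = n_max)
  cm <- row_cummean(trials)
  pop_mean <- rowsum(cm, rep(seq_len(reps), each = N)) / N
  err <- abs(pop_mean - mu_subjects) / mu_subjects
  eta <- apply(err, 2, quantile, probs = percentile, names = FALSE)
  new_error_curve(seq_len(n_max), eta, "population",
                  list(mu_subjects = mu_subjects,
                       sigma_subjects = sigma_subjects,
                       sigma_trials = sigma_trials, N = N, reps = reps,
                       percentile = percentile, seed = seed))
}

#' Simulated t-statistic curve for a two-condition comparison
#'
#' Draws `reps` pairs of populations of `N` subjects whose true means follow
#' a moment-matched bivariate lognormal ([bivariate_lognormal_spec()]) with
#' asymptotic correlation `r` (`r = 0` reproduces the unpaired design as the
#' zero-covariance special case). Each subject contributes `n_max` lognormal
#' trials around its own mean. For every `n`, the per-replicate mean and
#' c4-corrected SD across subjects of the cumulative amplitude differences
#' are averaged over replicates and combined into
#' \eqn{t(n, N) = \bar d / (s_d / \sqrt{N})}, comparable to
#' [t_statistic_design()].
#'
#' @param mu1,mu2 True condition means (mV).
#' @param sigma_subjects,sigma_trials Shared variability parameters (mV).
#' @param r Asymptotic correlation between conditions.
#' @param N Subjects per population.
#' @inheritParams simulate_single_subject_curve
#' @return A tibble of class `"mep_t_curve"` with columns `n`, `t`.
#' @export
simulate_t_curve <- function(mu1, mu2, sigma_subjects, sigma_trials, r,
                             N, n_max = 100, reps = 10000, seed = 1) {
  check_count(N, "N", min = 2)
  set.seed(seed)
  spec <- bivariate_lognormal_spec(mu1, mu2, sigma_subjects, r)
  n_rows <- reps * N
  means <- rbvlnorm_matched(n_rows, spec)
  t1 <- matrix(rlnorm_matched(n_rows * n_max, means$x1, sigma_trials),
               nrow = n_rows, ncol = n_max)
  t2 <- matrix(rlnorm_matched(n_rows * n_max, means$x2, sigma_trials),
               nrow = n_rows, ncol = n_max)
  d <- row_cummean(t1) - row_cummean(t2)
  grp <- rep(seq_len(reps), each = N)
  s <- rowsum(d, grp)
  s2 <- rowsum(d^2, grp)
  d_mean <- s / N
  d_sd <- sqrt(pmax(s2 - s^2 / N, 0) / (N - 1)) / c4(N)
  t_vals <- colMeans(d_mean) / (colMeans(d_sd) / sqrt(N))
  structure(
    tibble::tibble(n = seq_len(n_max), t = t_vals),
    class = c("mep_t_curve", class(tibble::tibble())),
    params = list(mu1 = mu1, mu2 = mu2, sigma_subjects = sigma_subjects,
                  sigma_trials = sigma_trials, r = r, N = N, reps = reps,
                  seed = seed)
  )
}
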