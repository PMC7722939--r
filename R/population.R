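#' Relative error of a population mean estimated from N subjects
#'
#' The subject-level analogue of [error_single()]:
#' \eqn{\eta(N) = z_{1-\alpha/2} CV_{subjects} / \sqrt{N}}, where
#' `cv_subjects` is the coefficient of variation of per-subject mean
#' amplitudes.
#'
#' @param N Number of subjects (>= 1, `Inf` allowed; vectorized).
#' @param cv_subjects Between-subject coefficient of variation (>= 0).
#' @param p_incl Probability of inclusion within the error.
#' @return Relative error (fraction).
#' @examples
#' error_population(20, 0.39) # ~0.171
#' @export
error_population <- function(N, cv_subjects, p_incl = 0.95) {
  check_count(N, "N")
  check_nonneg(cv_subjects, "cv_subjects")
  critical_value(p_incl) * cv_subjects / sqrt(N)
}

#' Between-subject SD observed with n trials per subject
#'
#' With finite trials the observed spread of subject means mixes true
#' between-subject variability with trial-sampling noise:
#' \eqn{\sigma_{subjects}^2(n) = \sigma_{subjects}^2 + \sigma_{trials}^2/n}.
#'
#' @param sigma_subjects Asymptotic (infinite-trial) between-subject SD (mV).
#' @param sigma_trials Pooled within-subject SD of single-trial amplitude (mV).
#' @param n Trials per subject (>= 1, `Inf` allowed; vectorized).
#' @return Observed between-subject SD at `n` trials (mV).
#' @examples
#' sigma_subjects_at_n(0.5, 0.5, 10)
#' sigma_subjects_at_n(0.5, 0.5, Inf)
#' @export
sigma_subjects_at_n <- function(sigma_subjects, sigma_trials, n) {
  check_nonneg(sigma_subjects, "sigma_subjects")
  check_nonneg(sigma_trials, "sigma_trials")
  check_count(n, "n")
  sqrt(sigma_subjects^2 + sigma_trials^2 / n)
}

#' Asymptotic between-subject SD from an observed decomposition
#'
#' Inverts [sigma_subjects_at_n()]: removes the trial-sampling contribution
#' \eqn{\sigma_{trials}^2/n} from the between-subject variance observed with
#' `n` trials per subject.
#'
#' @param sigma_obs_at_n Observed SD of subject means at `n` trials (mV).
#' @inheritParams sigma_subjects_at_n
#' @return Asymptotic between-subject SD (mV).
#' @section Degenerate decompositions:
#' When the observed variance does not exceed the trial-noise term
#' (\eqn{\sigma_{obs}^2(n) \le \sigma_{trials}^2/n}) the observed spread is
#' fully attributable to trial noise and the asymptotic SD is not
#' identifiable; an error of class `"mepplan_degenerate_error"` is raised.
#' @examples
#' asymptotic_sigma_subjects(sigma_subjects_at_n(0.5, 0.5, 10), 0.5, 10)
#' @export
asymptotic_sigma_subjects <- function(sigma_obs_at_n, sigma_trials, n) {
  check_nonneg(sigma_obs_at_n, "sigma_obs_at_n")
  check_nonneg(sigma_trials, "sigma_trials")
  check_count(n, "n")
  noise <- sigma_trials^2 / n
  if (any(sigma_obs_at_n^2 <= noise & !(sigma_obs_at_n^2 == 0 & noise == 0))) {
    abort(
      paste0(
        "Degenerate decomposition: observed between-subject variance does ",
        "not exceed the trial-noise term sigma_trials^2 / n."
      ),
      class = "mepplan_degenerate_error"
    )
  }
  sqrt(sigma_obs_at_n^2 - noise)
}

#' Population-mean error as a joint function of subjects and trials
#'
#' \deqn{\eta(N, n) = \frac{z_{1-\alpha/2}
#'   \sqrt{\sigma_{subjects}^2 + \sigma_{trials}^2/n}}
#'   {\mu_{subjects}\sqrt{N}}.}
#' At `n = Inf` this reduces to [error_population()] with
#' `cv_subjects = sigma_subjects / mu_subjects`.
#'
#' @param N Number of subjects (>= 1; vectorized).
#' @param n Trials per subject (>= 1, `Inf` allowed; vectorized).
#' @param mu_subjects True population mean amplitude (mV, > 0).
#' @inheritParams sigma_subjects_at_n
#' @param p_incl Probability of inclusion.
#' @return Relative error (fraction).
#' @examples
#' error_population_n(N = 20, n = c(5, 10, Inf),
#'                    mu_subjects = 1, sigma_subjects = 0.5, sigma_trials = 0.5)
#' @export
error_population_n <- function(N, n, mu_subjects, sigma_subjects,
                               sigma_trials, p_incl = 0.95) {
  check_count(N, "N")
  check_pos(mu_subjects, "mu_subjects")
  critical_value(p_incl) *
    sigma_subjects_at_n(sigma_subjects, sigma_trials, n) /
    (mu_subjects * sqrt(N))
}

#' Expected t statistic for a two-condition design with n trials per subject
#'
#' The t statistic of a paired comparison of two conditions measured on the
#' same `N` subjects with `n` trials each, under equal variances:
#' \deqn{t(N, n) = \frac{\mu_1 - \mu_2}
#'   {\sqrt{2[\sigma_{subjects}^2(1 - r) + \sigma_{trials}^2/n]/N}},}
#' where `r` is the asymptotic (infinite-trial) correlation between the two
#' conditions. `r = 0` gives the equal-N, equal-variance unpaired t statistic
#' with per-group variance \eqn{\sigma_{subjects}^2 + \sigma_{trials}^2/n}.
#'
#' @param mu1,mu2 Condition/group mean amplitudes (mV).
#' @param sigma_subjects Shared asymptotic between-subject SD (mV).
#' @param sigma_trials Shared pooled within-subject SD (mV).
#' @param r Asymptotic correlation between conditions, in \[-1, 1\];
#'   0 encodes the unpaired (between-subjects) design.
#' @param N Number of subjects per condition (>= 2).
#' @param n Trials per subject (>= 1, `Inf` allowed; vectorized).
#' @return Expected t statistic (real; antisymmetric in `mu1`, `mu2`).
#' @examples
#' t_statistic_design(1.4, 1.0, 0.5, 0.5, r = 0, N = 20, n = 100)
#' @export
t_statistic_design <- function(mu1, mu2, sigma_subjects, sigma_trials,
                               r, N, n) {
  check_count(N, "N", min = 2)
  check_count(n, "n")
  check_r(r)
  v <- pair_variance(sigma_subjects, sigma_trials, r, n)
  if (any(v <= 0)) {
    abort("Degenerate comparison: zero variance in the denominator.",
          class = "mepplan_degenerate_error")
  }
  (mu1 - mu2) / sqrt(2 * v / N)
}

#' Subjects needed to detect a difference with n trials per subject
#'
#' Normal-approximation sample size for the two-condition comparison:
#' \deqn{N_{opt}(n) = 2\,\frac{[\sigma_{subjects}^2 (1 - r) +
#'   \sigma_{trials}^2/n](z_{1-\alpha/2} + z_{1-\beta})^2}
#'   {(\mu_1 - \mu_2)^2}.}
#' With alpha = 0.05 and beta = 0.20 the multiplier
#' \eqn{2(z_{1-\alpha/2}+z_{1-\beta})^2} is about 15.7 (15.68 when the
#' conventional two-decimal value 2.80 is used for the z sum, which published
#' tables typically do; pass `z_sum = 2.80` to reproduce them).
#'
#' @inheritParams t_statistic_design
#' @param alpha Two-sided type-I error probability.
#' @param beta Type-II error probability (power `1 - beta`).
#' @param z_sum Optional override of \eqn{z_{1-\alpha/2} + z_{1-\beta}}
#'   (e.g. the printed 2.80); when given, `alpha` and `beta` are ignored.
#' @return Real-valued subject count per condition; reported counts should be
#'   rounded with `round_count(x, "ceil")` so the planned power is guaranteed.
#' @examples
#' sample_size(1.2, 1.0, 0.5, 0.5, r = 0.9, n = 10, z_sum = 2.80)
#' @export
sample_size <- function(mu1, mu2, sigma_subjects, sigma_trials, r, n,
                        alpha = 0.05, beta = 0.20, z_sum = NULL) {
  check_count(n, "n")
  check_r(r)
  if (any(mu1 == mu2)) {
    abort("`mu1` and `mu2` must differ (a zero difference needs infinite N).",
          class = "mepplan_domain_error")
  }
  zs <- z_sum %||% z_sum_power(alpha, beta)
  check_pos(zs, "z_sum")
  2 * pair_variance(sigma_subjects, sigma_trials, r, n) * zs^2 /
    (mu1 - mu2)^2
}

pair_variance <- function(sigma_subjects, sigma_trials, r, n) {
  check_nonneg(sigma_subjects, "sigma_subjects")
  check_nonneg(sigma_trials, "sigma_trials")
  sigma_subjects^2 * (1 - r) + sigma_trials^2 / n
}

check_r <- function(r) {
  if (!is.numeric(r) || any(is.na(r)) || any(abs(r) > 1)) {
    abort("`r` must lie in [-1, 1].", class = "mepplan_domain_error")
  }
  invisible(r)
}

#' Test-retest correlation attenuated by finite trials
#'
#' The correlation observed between two repeated measures, each estimated
#' from `n` trials, is attenuated relative to the asymptotic correlation `r`:
#' \deqn{r(n) = r\,\frac{\sigma_{subjects}^2}
#'   {\sigma_{subjects}^2 + \sigma_{trials}^2/n}.}
#' Increasing `n` can raise the observed reliability only up to `r`.
#'
#' @param r Asymptotic correlation in \[-1, 1\].
#' @inheritParams sigma_subjects_at_n
#' @return Attenuated correlation (|r(n)| <= |r|). If `sigma_subjects = 0`
#'   and `sigma_trials > 0` the observed correlation is 0.
#' @examples
#' reliability_at_n(0.9, 0.5, 0.5, 10)
#' @export
reliability_at_n <- function(r, sigma_subjects, sigma_trials, n) {
  check_r(r)
  check_nonneg(sigma_subjects, "sigma_subjects")
  check_nonneg(sigma_trials, "sigma_trials")
  check_count(n, "n")
  denom <- sigma_subjects^2 + sigma_trials^2 / n
  ifelse(denom == 0, r, r * sigma_subjects^2 / denom)
}

#' Classical correction for attenuation of an observed correlation
#'
#' Inverts [reliability_at_n()] using the observed between-subject SD:
#' \deqn{r = r(n)\,\frac{\sigma_{obs}^2(n)}
#'   {\sigma_{obs}^2(n) - \sigma_{trials}^2/n}.}
#' On noisy inputs the estimator can exceed \[-1, 1\]; out-of-bounds results
#' are returned unchanged with attribute `out_of_bounds = TRUE` and a warning
#' rather than clipped, so callers can decide.
#'
#' @param r_n Observed (attenuated) correlation at `n` trials.
#' @inheritParams asymptotic_sigma_subjects
#' @return Disattenuated correlation estimate, with logical attribute
#'   `out_of_bounds`.
#' @examples
#' disattenuate(reliability_at_n(0.9, 0.5, 0.5, 10),
#'              sigma_subjects_at_n(0.5, 0.5, 10), 0.5, 10)
#' @export
disattenuate <- function(r_n, sigma_obs_at_n, sigma_trials, n) {
  check_r(r_n)
  noise <- sigma_trials^2 / n
  denom <- sigma_obs_at_n^2 - noise
  if (any(denom <= 0 & !(sigma_obs_at_n == 0 & noise == 0))) {
    abort(
      paste0(
        "Degenerate decomposition: observed variance does not exceed ",
        "the trial-noise term sigma_trials^2 / n."
      ),
      class = "mepplan_degenerate_error"
    )
  }
  out <- ifelse(denom == 0 & sigma_obs_at_n == 0, r_n,
                r_n * sigma_obs_at_n^2 / denom)
  oob <- abs(out) > 1
  if (any(oob)) {
    warn("Disattenuated correlation outside [-1, 1]; see `out_of_bounds`.")
  }
  structure(out, out_of_bounds = oob)
}
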