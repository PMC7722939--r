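#' Trial counts from the n_max-bounded empirical definitions (deprecated)
#'
#' Two definitions of the "optimal" number of trials that have been used to
#' analyse cumulative-average convergence against the *sample* average:
#' inclusion within a confidence interval around the sample average
#' (`n_opt_ci`) and inclusion within a fixed percent difference from the
#' sample average (`n_opt_pctdiff`). Both are analytic functions of the total
#' number of trials collected, `n_max`, and are bounded above by it —
#' `n_opt_ci` does not depend on trial-to-trial variability at all. They are
#' provided so that planning reports can demonstrate this dependence; for
#' actual planning use [n_opt_trials()], which targets the *true* average.
#'
#' @param n_max Total number of trials collected (>= 1, `Inf` allowed).
#' @param alpha_ci Alpha of the confidence interval around the sample
#'   average (0.05 for the usual 95% c.i.).
#' @param p_incl Probability of inclusion defining the critical value of the
#'   cumulative-average criterion. Exactly one of `p_incl`, `z` is given.
#' @param z Alternative to `p_incl`: the inclusion critical value directly.
#' @param mu,sigma Sample mean and SD of single-trial amplitude (mV).
#' @param eta Acceptable relative difference (0.1 for +/-10%).
#'
#' @return Real-valued trial counts (round explicitly with [round_count()]).
#'   `n_opt_ci` is always `< n_max`; `n_opt_pctdiff` is `< n_max` whenever
#'   `sigma > 0`, and `0` when `sigma == 0` (no averaging needed).
#' @examples
#' n_opt_ci(100, alpha_ci = 0.05, z = 2.493) # ~61.8
#' n_opt_pctdiff(100, mu = 1, sigma = 0.5, eta = 0.1, z = 2.493) # ~60.8
#' @export
n_opt_ci <- function(n_max, alpha_ci = 0.05, p_incl = NULL, z = NULL) {
  check_count(n_max, "n_max")
  check_prob(alpha_ci, "alpha_ci")
  z <- resolve_z(p_incl, z)
  z_ci <- qnorm(1 - alpha_ci / 2)
  n_max / (1 + (z_ci / z)^2)
}

#' @rdname n_opt_ci
#' @export
n_opt_pctdiff <- function(n_max, mu, sigma, eta, p_incl = NULL, z = NULL) {
  check_count(n_max, "n_max")
  check_pos(mu, "mu")
  check_nonneg(sigma, "sigma")
  check_pos(eta, "eta")
  z <- resolve_z(p_incl, z)
  # sigma = 0 makes the second term infinite and the count 0: no averaging
  1 / (1 / n_max + (eta * mu / (z * sigma))^2)
}

resolve_z <- function(p_incl, z) {
  if (is.null(z) && is.null(p_incl)) {
    abort("Supply either `p_incl` or `z`.", class = "mepplan_domain_error")
  }
  if (!is.null(z)) {
    check_pos(z, "z")
    z
  } else {
    critical_value(p_incl)
  }
}

#' Trials needed to estimate a single subject's amplitude
#'
#' The number of trials at which the confidence interval of the cumulative
#' average around the *true* mean equals the acceptable relative error:
#' \deqn{n_{opt} = \left[\frac{z_{1-\alpha/2}}{\eta} CV_{trials}\right]^2.}
#' Unlike the empirical definitions ([n_opt_ci()]), this does not depend on
#' how many trials happen to have been collected.
#'
#' @param cv_trials Within-subject coefficient of variation of single-trial
#'   amplitude (SD/mean across trials), >= 0.
#' @param eta Acceptable relative error around the true mean (> 0);
#'   0.1 means +/-10%.
#' @param p_incl Probability that the estimate falls within `eta`.
#' @return Real-valued trial count; round with [round_count()]. With
#'   `cv_trials = 0.5`, `eta = 0.1`, `p_incl = 0.95` this is 96.04 trials.
#' @examples
#' n_opt_trials(0.5, eta = 0.1)
#' error_single(30, 0.5) # error implied by using only 30 trials
#' @seealso [error_single()], its inverse in `n`.
#' @export
n_opt_trials <- function(cv_trials, eta, p_incl = 0.95) {
  check_nonneg(cv_trials, "cv_trials")
  check_pos(eta, "eta")
  (critical_value(p_incl) * cv_trials / eta)^2
}

#' Relative error implied by estimating with n trials
#'
#' Solves the single-subject planning relation for the error:
#' \eqn{\eta(n) = z_{1-\alpha/2} CV_{trials} / \sqrt{n}}. This is the
#' half-width of the inclusion interval around the true mean, as a fraction
#' of the true mean, when the amplitude is estimated by averaging `n` trials.
#'
#' @param n Number of trials (> 0, `Inf` allowed; vectorized). Fractional
#'   values are accepted so the function is the exact inverse of
#'   [n_opt_trials()] everywhere.
#' @inheritParams n_opt_trials
#' @return Relative error (fraction, not percent); decreasing as
#'   \eqn{1/\sqrt{n}}.
#' @examples
#' error_single(c(20, 30, 96), 0.5)
#' @export
error_single <- function(n, cv_trials, p_incl = 0.95) {
  check_pos(n, "n")
  check_nonneg(cv_trials, "cv_trials")
  critical_value(p_incl) * cv_trials / sqrt(n)
}
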