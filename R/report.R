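#' Planning report from an estimated population
#'
#' Turns a fitted [estimate_population()] object into the three planning
#' tables an experimenter needs when designing a follow-up study:
#'
#' * `single_subject`: trials required per subject ([n_opt_trials()]) at the
#'   mean and the min/max of the per-subject coefficients of variation;
#' * `population_error`: relative error of the population mean
#'   ([error_population_n()]) over a grid of trial counts;
#' * `sample_size` (when a difference is specified): subjects required
#'   ([sample_size()]) over the trial grid, for the within-subjects design at
#'   the given correlation `r` and for the between-subjects design (`r = 0`).
#'
#' The difference to detect is given either explicitly as `delta_means =
#' c(mu1, mu2)` or by `conservative = TRUE`, which applies a conservative
#' construction to the estimate itself: the first mean is the lower inclusion
#' limit of the estimated population mean,
#' \eqn{\mu_1 = \hat\mu (1 - \hat\eta)} with \eqn{\hat\eta} the estimation
#' error at the recorded trial count, and the second is half of it,
#' \eqn{\mu_2 = \mu_1 / 2}.
#'
#' @param est An `"mep_population_estimate"`.
#' @param eta Acceptable single-subject relative error.
#' @param p_incl Probability of inclusion for the error computations.
#' @param alpha,beta,z_sum Power specification passed to [sample_size()].
#' @param delta_means Optional numeric pair `c(mu1, mu2)` of condition means
#'   (mV) for the sample-size table.
#' @param conservative If `TRUE`, build `delta_means` conservatively from the
#'   estimate as described above.
#' @param r Asymptotic correlation between the two conditions, required for
#'   the within-subjects sample-size column (e.g. a disattenuated split-half
#'   estimate).
#' @param n_grid Trial counts tabulated (may include `Inf`).
#' @param rounding Rounding policy for reported counts ([round_count()]).
#' @return An object of class `"mep_planning_report"`: a list of tibbles
#'   (`single_subject`, `population_error`, optionally `sample_size`) plus
#'   the echoed `params`.
#' @examples
#' fx <- generate_fixture(N = 20, n = 100, mu_subjects = 1.48,
#'                        sigma_subjects = 0.57, sigma_trials = 1.01, seed = 1)
#' planning_report(estimate_population(fx), delta_means = c(1.23, 0.62),
#'                 r = 0.61)
#' @export
planning_report <- function(est, eta = 0.1, p_incl = 0.95,
                            alpha = 0.05, beta = 0.20, z_sum = NULL,
                            delta_means = NULL, conservative = FALSE,
                            r = NULL,
                            n_grid = c(5, 10, 20, 30, 100, Inf),
                            rounding = "ceil") {
  stopifnot(inherits(est, "mep_population_estimate"))
  check_pos(eta, "eta")

  cvs <- c(mean = est$cv_trials_mean,
           min = est$cv_trials_range[1],
           max = est$cv_trials_range[2])
  single_subject <- tibble::tibble(
    cv_trials = unname(cvs),
    which = names(cvs),
    n_opt_raw = n_opt_trials(unname(cvs), eta, p_incl),
    n_opt = round_count(.data$n_opt_raw, rounding)
  )

  population_error <- tibble::tibble(
    n = n_grid,
    eta = error_population_n(est$N, n_grid, est$mu_subjects,
                             est$sigma_subjects, est$sigma_trials, p_incl),
    eta_percent = round(100 * .data$eta, 1)
  )

  if (isTRUE(conservative)) {
    eta_hat <- error_population(est$N, est$cv_subjects, p_incl)
    mu1 <- est$mu_subjects * (1 - eta_hat)
    delta_means <- c(mu1, mu1 / 2)
  }

  out <- list(single_subject = single_subject,
              population_error = population_error)

  if (!is.null(delta_means)) {
    if (is.null(r)) {
      abort(paste0("A within-subjects sample-size table needs the asymptotic ",
                   "correlation `r`."),
            class = "mepplan_domain_error")
    }
    check_r(r)
    ss <- function(r_use) {
      sample_size(delta_means[1], delta_means[2], est$sigma_subjects,
                  est$sigma_trials, r_use, n_grid,
                  alpha = alpha, beta = beta, z_sum = z_sum)
    }
    out$sample_size <- tibble::tibble(
      n = n_grid,
      N_within_raw = ss(r),
      N_within = round_count(.data$N_within_raw, rounding),
      N_between_raw = ss(0),
      N_between = round_count(.data$N_between_raw, rounding)
    )
  }

  out$params <- list(
    eta = eta, p_incl = p_incl, alpha = alpha, beta = beta, z_sum = z_sum,
    delta_means = delta_means, conservative = conservative, r = r,
    n_grid = n_grid, rounding = rounding,
    estimate = est[c("N", "n", "mu_subjects", "sigma_subjects_obs",
                     "sigma_subjects", "sigma_trials", "cv_subjects",
                     "cv_trials_mean", "cv_trials_range")]
  )
  structure(out, class = "mep_planning_report")
}

#' @export
print.mep_planning_report <- function(x, ...) {
  p <- x$params
  cat("<mep_planning_report>\n")
  cat(sprintf(
    "  inputs: N = %d, mu = %.3g mV, sigma_subjects = %.3g, sigma_trials = %.3g\n",
    p$estimate$N, p$estimate$mu_subjects, p$estimate$sigma_subjects,
    p$estimate$sigma_trials
  ))
  cat(sprintf("\nTrials per subject (eta = %.3g, p_incl = %.3g):\n",
              p$eta, p$p_incl))
  print(x$single_subject)
  cat("\nPopulation-mean error vs trials:\n")
  print(x$population_error)
  if (!is.null(x$sample_size)) {
    cat(sprintf("\nSubjects needed (mu1 = %.3g, mu2 = %.3g, r = %.3g):\n",
                p$delta_means[1], p$delta_means[2], p$r))
    print(x$sample_size)
  }
  invisible(x)
}
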