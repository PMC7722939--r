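# broom-style methods for the fitted objects.

#' Tidy a population estimate
#'
#' @param x An `"mep_population_estimate"`.
#' @param ... Unused.
#' @return A long tibble with columns `parameter`, `estimate`.
#' @method tidy mep_population_estimate
#' @export
tidy.mep_population_estimate <- function(x, ...) {
  tibble::tibble(
    parameter = c("mu_subjects", "sigma_subjects_obs", "sigma_subjects",
                  "sigma_trials", "cv_subjects", "cv_trials_mean",
                  "cv_trials_min", "cv_trials_max"),
    estimate = c(x$mu_subjects, x$sigma_subjects_obs, x$sigma_subjects,
                 x$sigma_trials, x$cv_subjects, x$cv_trials_mean,
                 x$cv_trials_range[1], x$cv_trials_range[2])
  )
}

#' @rdname tidy.mep_population_estimate
#' @return `glance()` returns a one-row tibble with the estimate and its
#'   design size (`N`, `n`, `degenerate`).
#' @method glance mep_population_estimate
#' @export
glance.mep_population_estimate <- function(x, ...) {
  tibble::tibble(
    N = x$N, n = x$n, mu_subjects = x$mu_subjects,
    sigma_subjects_obs = x$sigma_subjects_obs,
    sigma_subjects = x$sigma_subjects, sigma_trials = x$sigma_trials,
    cv_subjects = x$cv_subjects, cv_trials_mean = x$cv_trials_mean,
    degenerate = x$degenerate
  )
}

#' Tidy a split-half correlation
#'
#' @param x An `"mep_split_half"`.
#' @param ... Unused.
#' @return The leave-one-out diagnostic tibble (`subject_id`, `r_without`).
#' @method tidy mep_split_half
#' @export
tidy.mep_split_half <- function(x, ...) {
  x$leave_one_out
}

#' @rdname tidy.mep_split_half
#' @return `glance()` returns a one-row tibble with `r`, `N`, `block`.
#' @method glance mep_split_half
#' @export
glance.mep_split_half <- function(x, ...) {
  tibble::tibble(r = x$r, N = x$N, block = x$block)
}
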