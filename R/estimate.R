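#' Per-subject summary statistics of single-trial amplitudes
#'
#' Computes, for each subject in a tidy subject-by-trial table, the mean, SD
#' (n - 1 denominator), coefficient of variation and adjusted (bias-corrected)
#' sample skewness of its single-trial amplitudes.
#'
#' @param data A tidy tibble/data frame with columns `subject_id`,
#'   `trial_index`, `amplitude_mv` (see [read_trial_matrix()] and
#'   [generate_fixture()]).
#' @return A tibble with one row per subject: `subject_id`, `n_trials`,
#'   `mean_mv`, `sd_mv`, `cv`, `skewness` (NA with fewer than 3 trials).
#' @examples
#' fx <- generate_fixture(N = 4, n = 20, mu_subjects = 1,
#'                        sigma_subjects = 0.5, sigma_trials = 0.5, seed = 1)
#' summarize_subjects(fx)
#' @export
summarize_subjects <- function(data) {
  data <- validate_trial_matrix(data)
  counts <- dplyr::count(data, .data$subject_id)
  too_few <- counts$subject_id[counts$n < 2]
  if (length(too_few) > 0) {
    abort(paste0("Subject(s) with fewer than 2 trials: ",
                 paste(too_few, collapse = ", "), "."),
          class = "mepplan_domain_error")
  }
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_mv = mean(.data$amplitude_mv),
      sd_mv = sd(.data$amplitude_mv),
      cv = .data$sd_mv / .data$mean_mv,
      skewness = if (dplyr::n() >= 3) {
        e1071::skewness(.data$amplitude_mv, type = 2)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Estimate the population planning parameters from a trial table
#'
#' Mirrors the workflow of turning a recorded subject-by-trial amplitude
#' matrix into the quantities the planning equations need:
#' the population mean (mean of subject means), the observed between-subject
#' SD at the recorded number of trials, the pooled within-subject SD (square
#' root of the trial-count-weighted mean of per-subject variances), the
#' asymptotic between-subject SD obtained by removing the trial-noise term
#' \eqn{\sigma_{trials}^2/n} ([asymptotic_sigma_subjects()]), and the
#' between- and within-subject coefficients of variation. For ragged tables
#' the noise term uses the harmonic mean of per-subject trial counts, since
#' each subject mean carries error variance \eqn{\sigma_{trials}^2/n_i}.
#'
#' @inheritParams summarize_subjects
#' @return An object of class `"mep_population_estimate"`: a list with
#'   elements `N`, `n` (harmonic-mean trials per subject), `mu_subjects`,
#'   `sigma_subjects_obs`, `sigma_subjects` (asymptotic),
#'   `sigma_trials` (pooled), `cv_subjects`, `cv_trials_mean`,
#'   `cv_trials_range`, `degenerate` (flag), and the per-subject summary
#'   tibble `subjects`. If the observed between-subject variance does not
#'   exceed the trial-noise term, `sigma_subjects` is reported as 0 with
#'   `degenerate = TRUE` and a warning.
#' @examples
#' fx <- generate_fixture(N = 20, n = 100, mu_subjects = 1.48,
#'                        sigma_subjects = 0.57, sigma_trials = 1.01, seed = 1)
#' estimate_population(fx)
#' @export
estimate_population <- function(data) {
  subjects <- summarize_subjects(data)
  if (nrow(subjects) < 2) {
    abort("At least 2 subjects are required.", class = "mepplan_domain_error")
  }
  mu <- mean(subjects$mean_mv)
  sigma_obs <- sd(subjects$mean_mv)
  sigma_trials <- sqrt(weighted.mean(subjects$sd_mv^2, subjects$n_trials))
  n_harm <- 1 / mean(1 / subjects$n_trials)
  degenerate <- FALSE
  sigma_asym <- tryCatch(
    asymptotic_sigma_subjects(sigma_obs, sigma_trials, n_harm),
    mepplan_degenerate_error = function(cnd) {
      warn(paste0("Observed between-subject spread is fully attributable ",
                  "to trial noise; asymptotic SD reported as 0."))
      degenerate <<- TRUE
      0
    }
  )
  structure(
    list(
      N = nrow(subjects),
      n = n_harm,
      mu_subjects = mu,
      sigma_subjects_obs = sigma_obs,
      sigma_subjects = sigma_asym,
      sigma_trials = sigma_trials,
      cv_subjects = sigma_obs / mu,
      cv_trials_mean = mean(subjects$cv),
      cv_trials_range = range(subjects$cv),
      degenerate = degenerate,
      subjects = subjects
    ),
    class = "mep_population_estimate"
  )
}

#' @export
print.mep_population_estimate <- function(x, ...) {
  cat("<mep_population_estimate>\n")
  cat(sprintf("  %d subjects, %.4g trials/subject (harmonic mean)\n",
              x$N, x$n))
  cat(sprintf("  mu_subjects        %.4g mV\n", x$mu_subjects))
  cat(sprintf("  sigma_subjects(n)  %.4g mV (observed)\n",
              x$sigma_subjects_obs))
  cat(sprintf("  sigma_subjects     %.4g mV (asymptotic%s)\n",
              x$sigma_subjects,
              if (x$degenerate) "; degenerate decomposition" else ""))
  cat(sprintf("  sigma_trials       %.4g mV (pooled)\n", x$sigma_trials))
  cat(sprintf("  CV_subjects        %.3g\n", x$cv_subjects))
  cat(sprintf("  CV_trials          %.3g (range %.3g-%.3g)\n",
              x$cv_trials_mean, x$cv_trials_range[1], x$cv_trials_range[2]))
  invisible(x)
}

#' Split-half correlation of block-mean amplitudes
#'
#' Pearson correlation, across subjects, between the mean amplitude of the
#' first `block` trials and the mean of the next `block` trials (trial order
#' as recorded; no shuffling). Because each block mean carries trial-sampling
#' noise, this correlation is attenuated exactly as [reliability_at_n()] with
#' `n = block` predicts, and can serve as a lower bound on the asymptotic
#' reliability. A leave-one-out correlation vector is returned as an outlier
#' diagnostic; no observation is ever removed automatically.
#'
#' @inheritParams summarize_subjects
#' @param block Trials per half (each subject needs at least `2 * block`).
#' @return An object of class `"mep_split_half"`: a list with `r`, `block`,
#'   `N`, a `block_means` tibble (`subject_id`, `mean_first`, `mean_second`)
#'   and a `leave_one_out` tibble (`subject_id`, `r_without`).
#' @examples
#' fx <- generate_fixture(N = 12, n = 40, mu_subjects = 1,
#'                        sigma_subjects = 0.5, sigma_trials = 0.5, seed = 1)
#' split_half_r(fx, block = 20)
#' @export
split_half_r <- function(data, block) {
  data <- validate_trial_matrix(data)
  check_count(block, "block")
  counts <- dplyr::count(data, .data$subject_id)
  too_few <- counts$subject_id[counts$n < 2 * block]
  if (length(too_few) > 0) {
    abort(paste0("Subject(s) with fewer than 2 * block = ", 2 * block,
                 " trials: ", paste(too_few, collapse = ", "), "."),
          class = "mepplan_domain_error")
  }
  if (nrow(counts) < 3) {
    abort("At least 3 subjects are required for a split-half correlation.",
          class = "mepplan_domain_error")
  }
  block_means <- data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::summarise(
      mean_first = mean(.data$amplitude_mv[seq_len(block)]),
      mean_second = mean(.data$amplitude_mv[block + seq_len(block)]),
      .groups = "drop"
    )
  r <- cor(block_means$mean_first, block_means$mean_second)
  loo <- purrr::map_dbl(seq_len(nrow(block_means)), function(i) {
    cor(block_means$mean_first[-i], block_means$mean_second[-i])
  })
  structure(
    list(
      r = r, block = block, N = nrow(block_means),
      block_means = block_means,
      leave_one_out = tibble::tibble(
        subject_id = block_means$subject_id, r_without = loo
      )
    ),
    class = "mep_split_half"
  )
}

#' @export
print.mep_split_half <- function(x, ...) {
  cat(sprintf(
    "<mep_split_half> r = %.3f (N = %d subjects, %d trials per half)\n",
    x$r, x$N, x$block
  ))
  cat(sprintf("  leave-one-out range: %.3f to %.3f\n",
              min(x$leave_one_out$r_without),
              max(x$leave_one_out$r_without)))
  invisible(x)
}
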