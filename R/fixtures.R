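#' Generate a synthetic subject-by-trial amplitude table
#'
#' Draws a synthetic dataset with the same hierarchy the population simulator
#' uses: subject true means are lognormal (`mu_subjects`, `sigma_subjects`)
#' and each subject's single-trial amplitudes are lognormal around its own
#' mean with SD `sigma_trials`. Intended as a stand-in for real recordings
#' when exercising the estimation routines.
#'
#' @param N Number of subjects.
#' @param n Trials per subject.
#' @param mu_subjects,sigma_subjects,sigma_trials Population parameters (mV).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tidy tibble with columns `subject_id` (character),
#'   `trial_index` (1-based integer) and `amplitude_mv`.
#' @examples
#' generate_fixture(N = 5, n = 10, mu_subjects = 1.48,
#'                  sigma_subjects = 0.57, sigma_trials = 1.01, seed = 1)
#' @export
generate_fixture <- function(N, n, mu_subjects, sigma_subjects, sigma_trials,
                             seed = 1) {
  check_count(N, "N")
  check_count(n, "n")
  check_pos(mu_subjects, "mu_subjects")
  set.seed(seed)
  subject_means <- rlnorm_matched(N, mu_subjects, sigma_subjects)
  amps <- rlnorm_matched(N * n, rep(subject_means, each = n), sigma_trials)
  tibble::tibble(
    subject_id = rep(sprintf("S%03d", seq_len(N)), each = n),
    trial_index = rep(seq_len(n), times = N),
    amplitude_mv = amps
  )
}

#' Generate a synthetic two-measure (paired) amplitude table
#'
#' As [generate_fixture()], but each subject has two true means drawn from a
#' moment-matched bivariate lognormal with asymptotic correlation `r`
#' (e.g. two sessions, or two stimulation intensities). Useful for studying
#' reliability attenuation: the correlation of `n`-trial averages between the
#' two measures follows [reliability_at_n()].
#'
#' @inheritParams generate_fixture
#' @param mu1,mu2 True means of the two measures (mV).
#' @param r Asymptotic correlation between the two measures.
#' @return A tidy tibble with columns `subject_id`, `measure` (1 or 2),
#'   `trial_index`, `amplitude_mv`.
#' @export
generate_paired_fixture <- function(N, n, mu1, mu2, sigma_subjects,
                                    sigma_trials, r, seed = 1) {
  check_count(N, "N")
  check_count(n, "n")
  set.seed(seed)
  spec <- bivariate_lognormal_spec(mu1, mu2, sigma_subjects, r)
  means <- rbvlnorm_matched(N, spec)
  draw <- function(m) rlnorm_matched(N * n, rep(m, each = n), sigma_trials)
  ids <- rep(sprintf("S%03d", seq_len(N)), each = n)
  idx <- rep(seq_len(n), times = N)
  dplyr::bind_rows(
    tibble::tibble(subject_id = ids, measure = 1L, trial_index = idx,
                   amplitude_mv = draw(means$x1)),
    tibble::tibble(subject_id = ids, measure = 2L, trial_index = idx,
                   amplitude_mv = draw(means$x2))
  )
}

#' Read a subject-by-trial amplitude table from CSV
#'
#' Accepts either the tidy layout (`subject_id,trial_index,amplitude_mv`,
#' 1-based trial indices, amplitudes in mV) or a wide layout with one row per
#' subject (`subject_id,trial_1,...,trial_n`; missing cells allowed for
#' ragged data).
#'
#' @param path Path to a CSV file (comma-separated, header required,
#'   dot decimal separator).
#' @param format `"tidy"` or `"wide"`.
#' @return A tidy tibble with columns `subject_id`, `trial_index`,
#'   `amplitude_mv`, trial order preserved.
#' @export
read_trial_matrix <- function(path, format = c("tidy", "wide")) {
  format <- match.arg(format)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (format == "wide") {
    if (!"subject_id" %in% names(data)) {
      abort("Wide CSV must have a `subject_id` column.",
            class = "mepplan_io_error")
    }
    data <- tidyr::pivot_longer(
      data, -"subject_id",
      names_to = "trial_index", names_prefix = "trial_",
      values_to = "amplitude_mv", values_drop_na = TRUE
    )
    data$trial_index <- as.integer(data$trial_index)
    data <- dplyr::arrange(data, .data$subject_id, .data$trial_index)
  }
  validate_trial_matrix(data)
}

validate_trial_matrix <- function(data) {
  required <- c("subject_id", "trial_index", "amplitude_mv")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing, collapse = ", "), "."),
          class = "mepplan_io_error")
  }
  if (any(!is.finite(data$amplitude_mv)) || any(data$amplitude_mv < 0)) {
    abort("Amplitudes must be finite and non-negative (mV).",
          class = "mepplan_io_error")
  }
  tibble::as_tibble(data[, union(required, names(data))])
}
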