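# ggplot2 convenience layers for the simulated curves and planning tables.

#' Plot a simulated error-percentile curve against its analytic prediction
#'
#' @param object An `"mep_error_curve"` from
#'   [simulate_single_subject_curve()] or [simulate_population_curve()].
#' @param ... Unused.
#' @return A ggplot: simulated relative error vs trials, with the analytic
#'   curve ([error_single()] or [error_population_n()]) overlaid.
#' @method autoplot mep_error_curve
#' @export
autoplot.mep_error_curve <- function(object, ...) {
  p <- attr(object, "params")
  kind <- attr(object, "kind")
  analytic <- if (kind == "single_subject") {
    error_single(object$n, p$cv, p$percentile)
  } else {
    error_population_n(p$N, object$n, p$mu_subjects, p$sigma_subjects,
                       p$sigma_trials, p$percentile)
  }
  df <- dplyr::bind_rows(
    tibble::tibble(n = object$n, eta = object$eta, source = "simulated"),
    tibble::tibble(n = object$n, eta = analytic, source = "analytic")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$eta,
                                   linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trials per subject (n)",
                  y = "relative error η",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated t curve against its analytic prediction
#'
#' @param object An `"mep_t_curve"` from [simulate_t_curve()].
#' @param ... Unused.
#' @return A ggplot of the expected t statistic vs trials.
#' @method autoplot mep_t_curve
#' @export
autoplot.mep_t_curve <- function(object, ...) {
  p <- attr(object, "params")
  analytic <- t_statistic_design(p$mu1, p$mu2, p$sigma_subjects,
                                 p$sigma_trials, p$r, p$N, object$n)
  df <- dplyr::bind_rows(
    tibble::tibble(n = object$n, t = object$t, source = "simulated"),
    tibble::tibble(n = object$n, t = analytic, source = "analytic")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$t,
                                   linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trials per subject (n)", y = "t statistic",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sample-size table of a planning report
#'
#' @param report An `"mep_planning_report"` containing a `sample_size` table.
#' @return A ggplot of subjects needed vs trials per subject, for the
#'   within- and between-subjects designs (finite trial counts only).
#' @export
plot_sample_size <- function(report) {
  stopifnot(inherits(report, "mep_planning_report"))
  if (is.null(report$sample_size)) {
    abort("Report has no sample-size table; supply `delta_means` and `r`.",
          class = "mepplan_domain_error")
  }
  df <- report$sample_size |>
    dplyr::filter(is.finite(.data$n)) |>
    tidyr::pivot_longer(c("N_within", "N_between"),
                        names_to = "design", values_to = "N") |>
    dplyr::mutate(design = dplyr::recode(.data$design,
                                         N_within = "within-subjects",
                                         N_between = "between-subjects"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$N,
                                   colour = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "trials per subject (n)", y = "subjects needed",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
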