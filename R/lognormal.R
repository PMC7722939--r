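#' Moment-matched lognormal parameters
#'
#' Log-scale parameters of a lognormal distribution whose arithmetic mean and
#' SD equal the targets exactly:
#' \deqn{\mu_{log} = \log\!\left(\frac{m^2}{\sqrt{m^2 + s^2}}\right), \qquad
#'   \sigma^2_{log} = \log\!\left(1 + \frac{s^2}{m^2}\right).}
#' Single-trial MEP amplitudes are right-skewed; the lognormal with these
#' parameters is the generating distribution used throughout the simulation
#' engine.
#'
#' @param mean Target arithmetic mean (mV, > 0).
#' @param sd Target arithmetic SD (mV, >= 0; 0 gives a point mass).
#' @return An object of class `"lognormal_spec"`: a list with `target_mean`,
#'   `target_sd`, `log_mean`, `log_var` and the implied `skewness`
#'   \eqn{(e^{\sigma^2_{log}} + 2)\sqrt{e^{\sigma^2_{log}} - 1}}.
#' @examples
#' lognormal_spec(1, 0.5)
#' lognormal_spec(1, 1)$skewness # 4: heavily skewed
#' @export
lognormal_spec <- function(mean, sd) {
  check_pos(mean, "mean")
  check_nonneg(sd, "sd")
  log_var <- log(1 + sd^2 / mean^2)
  structure(
    list(
      target_mean = mean,
      target_sd = sd,
      log_mean = log(mean^2 / sqrt(mean^2 + sd^2)),
      log_var = log_var,
      skewness = (exp(log_var) + 2) * sqrt(exp(log_var) - 1)
    ),
    class = "lognormal_spec"
  )
}

#' @export
print.lognormal_spec <- function(x, ...) {
  cat(sprintf(
    "<lognormal_spec> mean %.4g, sd %.4g (log-scale mu %.5f, var %.5f, skewness %.3f)\n",
    x$target_mean, x$target_sd, x$log_mean, x$log_var, x$skewness
  ))
  invisible(x)
}

#' Moment-matched bivariate lognormal parameters
#'
#' Log-scale parameters of a bivariate lognormal whose marginals have
#' arithmetic means `mean1`, `mean2` and shared SD `sd`, and whose arithmetic
#' covariance is `r * sd^2` (so `r` is the correlation between the two
#' lognormal margins). The log-scale covariance is
#' \deqn{\rho\sigma_1\sigma_2 =
#'   \log\!\left(1 + \frac{r\,s^2}{m_1 m_2}\right).}
#'
#' @param mean1,mean2 Marginal arithmetic means (mV, > 0).
#' @param sd Shared marginal arithmetic SD (mV, >= 0).
#' @param r Target correlation between the two margins, in \[-1, 1\].
#' @return An object of class `"bivariate_lognormal_spec"`: marginal
#'   [lognormal_spec()]s plus `log_cov` and the log-scale correlation
#'   `log_rho`.
#' @examples
#' bivariate_lognormal_spec(1.2, 1.0, 0.5, r = 0.9)
#' @export
bivariate_lognormal_spec <- function(mean1, mean2, sd, r) {
  check_r(r)
  m1 <- lognormal_spec(mean1, sd)
  m2 <- lognormal_spec(mean2, sd)
  log_cov <- log(1 + r * sd^2 / (mean1 * mean2))
  if (sd == 0) {
    log_rho <- 0
  } else {
    log_rho <- log_cov / sqrt(m1$log_var * m2$log_var)
  }
  if (abs(log_rho) > 1) {
    abort("Log-scale covariance matrix is not positive semi-definite.",
          class = "mepplan_domain_error")
  }
  structure(
    list(marginal1 = m1, marginal2 = m2, log_cov = log_cov,
         log_rho = log_rho, r = r),
    class = "bivariate_lognormal_spec"
  )
}

#' @export
print.bivariate_lognormal_spec <- function(x, ...) {
  cat(sprintf(
    "<bivariate_lognormal_spec> means (%.4g, %.4g), sd %.4g, r %.3g (log-cov %.5f)\n",
    x$marginal1$target_mean, x$marginal2$target_mean,
    x$marginal1$target_sd, x$r, x$log_cov
  ))
  invisible(x)
}

#' Finite-sample bias correction for the sample standard deviation
#'
#' Series approximation of the c4 correction factor: the sample SD divided by
#' `c4(N)` is (nearly) unbiased for the population SD under normality:
#' \deqn{c_4(N) = 1 - \frac{1}{4N} - \frac{7}{32N^2} - \frac{19}{128N^3}.}
#'
#' @param N Sample size (>= 2; vectorized, `Inf` allowed).
#' @return Correction factor in (0, 1), increasing to 1 as N grows.
#' @examples
#' c4(10)
#' @export
c4 <- function(N) {
  check_count(N, "N", min = 2)
  1 - 1 / (4 * N) - 7 / (32 * N^2) - 19 / (128 * N^3)
}

# Draws matching a lognormal_spec; vectorized over a per-draw mean so the
# hierarchical generators can pass one mean per subject.
rlnorm_matched <- function(n_draws, mean, sd) {
  if (all(sd == 0)) {
    return(rep(mean, length.out = n_draws))
  }
  log_var <- log(1 + sd^2 / mean^2)
  rlnorm(n_draws,
         meanlog = log(mean^2 / sqrt(mean^2 + sd^2)),
         sdlog = sqrt(log_var))
}

# Correlated pair of lognormal vectors per a bivariate_lognormal_spec.
rbvlnorm_matched <- function(n_draws, spec) {
  s1 <- sqrt(spec$marginal1$log_var)
  s2 <- sqrt(spec$marginal2$log_var)
  u1 <- rnorm(n_draws)
  u2 <- rnorm(n_draws)
  rho <- spec$log_rho
  z1 <- spec$marginal1$log_mean + s1 * u1
  z2 <- spec$marginal2$log_mean + s2 * (rho * u1 + sqrt(1 - rho^2) * u2)
  list(x1 = exp(z1), x2 = exp(z2))
}
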