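#' Two-sided standard-normal critical value for an inclusion probability
#'
#' The planning equations express "the estimate falls within a relative error
#' eta of the true value with probability `p_incl`" through the standard-normal
#' critical value \eqn{z_{1-\alpha/2}} with \eqn{\alpha = 1 - p_{incl}}.
#'
#' @param p_incl Probability of inclusion, strictly between 0 and 1.
#'   `p_incl = 0.95` gives the familiar 1.96.
#'
#' @return The \eqn{(1 - \alpha/2)} quantile of the standard normal
#'   distribution (vectorized over `p_incl`).
#' @examples
#' critical_value(0.95)
#' critical_value(0.6827) # ~1: two-sided one-sigma coverage
#' @export
critical_value <- function(p_incl) {
  check_prob(p_incl, "p_incl")
  qnorm(1 - (1 - p_incl) / 2)
}

#' Combined critical value for a two-sided test at power 1 - beta
#'
#' @param alpha Two-sided type-I error probability.
#' @param beta Type-II error probability (power is `1 - beta`).
#' @return \eqn{z_{1-\alpha/2} + z_{1-\beta}}; about 2.80 for the
#'   conventional alpha = 0.05, beta = 0.20.
#' @export
z_sum_power <- function(alpha = 0.05, beta = 0.20) {
  check_prob(alpha, "alpha")
  check_prob(beta, "beta")
  qnorm(1 - alpha / 2) + qnorm(1 - beta)
}

#' Round a planned count
#'
#' All planning equations return real-valued trial/subject counts; rounding is
#' a separate, explicit reporting step. `"ceil"` is the conservative default
#' (an integer count that still guarantees the stated error or power);
#' `"nearest"` reproduces the convention used in some published tables;
#' `"raw"` passes the value through.
#'
#' @param x Non-negative numeric (may be `Inf`).
#' @param policy One of `"ceil"`, `"nearest"`, `"raw"`.
#' @return Rounded counts (numeric, so that `Inf` survives).
#' @examples
#' round_count(96.04, "nearest")
#' round_count(32.30, "ceil")
#' @export
round_count <- function(x, policy = c("ceil", "nearest", "raw")) {
  policy <- match.arg(policy)
  check_nonneg(x, "x")
  # counts come out of floating-point formulas; snap values a few ulps above
  # an integer back down before ceiling so 196 + 3e-14 stays 196
  switch(policy,
    raw = x,
    ceil = ceiling(signif(x, 12)),
    nearest = round(signif(x, 12))
  )
}
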