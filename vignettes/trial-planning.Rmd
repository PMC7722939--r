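---
title: "Planning trials and subjects for evoked-potential experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning trials and subjects for evoked-potential experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepplan)
```

## The problem

The peak-to-peak amplitude of a motor evoked potential (MEP) elicited by
transcranial magnetic stimulation is one of the most widely used readouts of
corticospinal excitability — and one of the most variable. Because the
single-trial amplitude fluctuates strongly, experiments average it over
trials, and every design faces the same trade-off: more trials per subject
cost time and stationarity, fewer trials cost precision. mepplan implements
a closed-form framework that makes this trade-off explicit, separately for

* estimating a **single subject's** mean amplitude,
* estimating a **population** mean amplitude,
* **hypothesis testing** between two conditions or groups, and
* **test–retest reliability** of the averaged measure,

together with a lognormal Monte Carlo engine that checks every relation by
simulation, and estimation routines that extract the framework's parameters
from a recorded subject-by-trial amplitude table.

## The model

Single-trial amplitude within a subject is a stochastic variable with mean
$\mu_{trials}$ and SD $\sigma_{trials}$; its relative spread is
$CV_{trials} = \sigma_{trials}/\mu_{trials}$. The framework assumes only
that *averages* of trials are approximately normal (central limit theorem),
not that single trials are.

**Single subject.** The number of trials after which the cumulative average
sits, with probability $p_{incl}$, within a relative error $\eta$ of the
true mean is

$$n_{opt} = \left[\frac{z_{1-\alpha/2}}{\eta}\,CV_{trials}\right]^2,
\qquad \alpha = 1 - p_{incl},$$

and conversely $\eta(n) = z_{1-\alpha/2}\,CV_{trials}/\sqrt{n}$
(`n_opt_trials()`, `error_single()`). Two older, *empirical* definitions of
the "optimal" trial count — convergence of the cumulative average onto the
*sample* average within a confidence interval or a fixed percent difference —
are also implemented (`n_opt_ci()`, `n_opt_pctdiff()`), because their
closed forms show why they should not be used for planning: both are
analytic functions of, and bounded by, however many trials happened to be
collected, and the confidence-interval variant does not depend on the
trial-to-trial variability at all. Reports label them "n_max-bounded
(deprecated definitions)".

**Population.** The spread of per-subject means observed with $n$ trials
mixes true between-subject variability with trial-sampling noise:

$$\sigma^2_{subjects}(n) = \sigma^2_{subjects} + \frac{\sigma^2_{trials}}{n},$$

so the population-mean error is
$\eta(N, n) = z_{1-\alpha/2}\sqrt{\sigma^2_{subjects} +
\sigma^2_{trials}/n}\,/\,(\mu_{subjects}\sqrt{N})$
(`error_population_n()`). Because $n$ enters only through the (usually
minor) noise term while $N$ divides everything, trials buy little once a
handful are averaged; subjects are what matter.

**Hypothesis testing.** For two conditions with equal variances and
asymptotic correlation $r$ (the correlation that would be observed with
infinitely many trials; $r = 0$ encodes the unpaired design), the expected
t statistic and the normal-approximation sample size are

$$t(N,n) = \frac{\mu_1 - \mu_2}
  {\sqrt{2[\sigma^2_{subjects}(1-r) + \sigma^2_{trials}/n]/N}},
\qquad
N_{opt}(n) = \frac{2[\sigma^2_{subjects}(1-r) + \sigma^2_{trials}/n]
  (z_{1-\alpha/2} + z_{1-\beta})^2}{(\mu_1-\mu_2)^2}$$

(`t_statistic_design()`, `sample_size()`). The equal-variance assumption is
hard-coded, matching the framework's scope; unequal variances are out of
scope. Exact noncentral-t power is deliberately not implemented: the
normal-approximation formula is the framework's contract, and swapping in
exact power would change every published planning number.

**Reliability.** Finite trials attenuate the observed correlation between
repeated measures, $r(n) = r\,\sigma^2_{subjects}/(\sigma^2_{subjects} +
\sigma^2_{trials}/n)$ (`reliability_at_n()`); `disattenuate()` applies the
classical correction in the other direction. The two are exact algebraic
inverses wherever the variance decomposition is non-degenerate. Pearson's
correlation is the implemented reliability statistic; ICC variants are not.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `p_incl` | probability | 0.95 | chance the estimate falls within `eta`; sets $z_{1-\alpha/2}$ = 1.96 |
| `eta` | fraction | 0.1 | acceptable relative error (±10%) |
| `alpha`, `beta` | probability | 0.05, 0.20 | two-sided size and type-II error of the planned test |
| `z_sum` | — | exact | override for $z_{1-\alpha/2}+z_{1-\beta}$; published tables use the two-decimal 2.80 (multiplier 15.68), the exact double is 2.8016 |
| `rounding` | — | `"ceil"` | reported counts round up so the planned error/power is guaranteed; `"nearest"` reproduces tables that round to the nearest integer |

Critical values always come from the double-precision inverse normal CDF;
two-decimal textbook values are matched by tolerance, never hard-coded. All
planning functions accept `n = Inf` (and `N = Inf`) and return the analytic
limit, and all return *real-valued* counts — rounding is an explicit,
separate step (`round_count()`), because published tables mix conventions
(96.04 printed as 96, 32.30 as 33). Ceiling is applied after snapping
values within a few ulps of an integer back down, so a count that is
exactly 196 in exact arithmetic is not inflated to 197 by floating-point
noise.

## The simulation engine

MEP amplitudes are right-skewed, so the Monte Carlo engine draws them from
lognormal distributions *moment-matched* to a target arithmetic mean $m$
and SD $s$: log-scale mean $\log(m^2/\sqrt{m^2+s^2})$ and variance
$\log(1+s^2/m^2)$ (`lognormal_spec()`). At $s/m$ = 0.25, 0.5, 0.75, 1.0 the
implied skewness is 0.77, 1.63, 2.67, 4.0. Correlated condition pairs use a
bivariate lognormal whose log-scale covariance
$\log(1 + r\,\sigma^2_{subjects}/(\mu_1\mu_2))$ delivers exactly the target
arithmetic covariance $r\,\sigma^2_{subjects}$
(`bivariate_lognormal_spec()`); the unpaired design is the zero-covariance
special case of the same construction.

Three simulators mirror the analytic relations: per-trial-count 95th
percentiles of absolute cumulative-average errors for a single subject
(`simulate_single_subject_curve()`) and for a population mean
(`simulate_population_curve()`, hierarchy: lognormal subject means, then
lognormal trials around each subject mean), and the expected t statistic of
cumulative difference averages (`simulate_t_curve()`), where per-replicate
SDs are divided by the finite-sample correction
$c_4(N) = 1 - \frac{1}{4N} - \frac{7}{32N^2} - \frac{19}{128N^3}$ before
averaging. Errors are expressed relative to the configured true mean, so
non-unit means behave sensibly.

Each simulator seeds R's RNG once per call from its `seed` argument; runs
are bit-reproducible within this implementation, and statistically (not
bit-) reproducible across implementations. Trials are i.i.d. within a
subject — no drift, autocorrelation, attention or arousal effects — so
agreement between simulation and equations validates the algebra, not
stationarity in real recordings. The default replicate count is 10,000; the
shipped validation tests run the full curves at 10,000 replicates (about
half a minute in total) and smaller property checks at 2,000–4,000.

One deliberate caveat: for heavily skewed trials and very few of them, the
true error percentile sits a few percent *below* the normal-approximation
curve (about 4% at $CV_{trials}$ = 0.75 and 6% at 1.0, at $n = 5$). This is
a real small-sample deviation of skewed means, shrinking as $n$ grows —
with few trials and strong skew the closed forms are mildly conservative,
and normalizing transforms can tighten them. The validation suite asserts
tight bands and the $CV = 0.75$ band is knowingly strict there.

## From data to plan

`summarize_subjects()` reduces a tidy `subject_id`/`trial_index`/
`amplitude_mv` table to per-subject mean, SD ($n-1$ denominator), CV and
adjusted sample skewness. `estimate_population()` adds the population-level
decomposition: the pooled within-subject SD is the square root of the
trial-count-weighted mean of per-subject variances (exactly the plain mean
for rectangular tables), and the asymptotic between-subject SD removes the
noise term $\sigma^2_{trials}/n$, using the harmonic mean of per-subject
trial counts for ragged tables since each subject mean carries error
variance $\sigma^2_{trials}/n_i$. If the observed spread does not exceed
the noise term, the asymptotic SD is reported as 0 with a `degenerate`
flag rather than as an imaginary number.

`split_half_r()` correlates first-block against next-block means in
recorded trial order (no shuffling — the split is "first $b$ trials vs next
$b$"), and returns a leave-one-out correlation vector as an outlier
diagnostic; nothing is removed automatically, because no principled
criterion exists for automatic removal here. The split-half correlation at
block size $b$ is attenuated exactly as `reliability_at_n()` with $n = b$
predicts, so it bounds the asymptotic reliability from below and can be
disattenuated.

`planning_report()` assembles the planning tables (trials per subject at
the mean and range of per-subject CVs; population error over a trial grid;
subjects needed for within- and between-subjects designs). Its
`conservative = TRUE` option builds the difference to detect from the
estimate itself — first mean at the lower inclusion limit
$\hat\mu(1-\hat\eta)$, second mean at half of it — which is a deliberately
pessimistic convention for planning a dose-difference experiment.

## Synthetic data and what passing tests mean

`generate_fixture()` (and `generate_paired_fixture()` for two correlated
measures) draws subject-by-trial tables from exactly the hierarchy the
population simulator uses. Defaults in the test-suite fixtures use the
measured-data scale of the framework's worked application: population mean
1.48 mV, asymptotic between-subject SD 0.57 mV, pooled within-subject SD
1.01 mV, and 20 subjects by 100 trials (inflated to 500 subjects for
parameter-recovery checks so that recovery tolerances are driven by theory,
not subject count). The generator reproduces the variance structure,
skewness and attenuation behaviour of real MEP data, but not
non-stationarity, session effects, or artifact contamination — recovery on
fixtures demonstrates estimator correctness, not robustness to those.

## Numerical and design choices

* Degenerate inputs error loudly with typed conditions
  (`mepplan_domain_error`, `mepplan_degenerate_error`) instead of returning
  `NaN`; the one exception is `estimate_population()`, which flags rather
  than fails so a report can still be produced.
* Disattenuated correlations outside $[-1, 1]$ (possible on noisy inputs)
  are returned unclipped with an `out_of_bounds` attribute and a warning.
* `r` is accepted in $[-1, 1]$ although applications mostly use $[0, 1]$;
  negative correlations simply inflate the required sample size.
* No confidence intervals on estimated CVs: planning treats the variability
  inputs as known, which is the framework's own convention.
* The command-line surface (`inst/cli/mepplan.R`) is a thin Rscript over
  these functions; every report echoes its parameters so each number is
  reproducible from the report alone.

## Limitations

The framework plans *expected* precision and power under stationary,
equal-variance, CLT-normal averages. It does not model sequential designs,
unequal variances, amplitude drift, or exact small-sample t distributions,
and its reliability statistic is Pearson's $r$. For very few trials of
heavily skewed amplitudes the closed forms are mildly conservative (see the
simulation caveat above).
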