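# mepplan

Trial-count and sample-size planning for trial-averaged evoked-potential
experiments — developed around TMS motor evoked potentials (MEPs), but
applicable to any measure that is averaged over trials within subjects and
over subjects within populations (evoked responses, reaction times, …).

MEP amplitude is highly variable from pulse to pulse, so experiments
average it over trials. How many trials are enough? mepplan answers that
with a small set of closed-form relations between the number of trials
`n`, the number of subjects `N`, the within-subject variability
(`CV_trials = σ_trials/μ_trials`) and the between-subject variability
(`σ_subjects`):

* **Single subject** — trials needed for a relative error η at inclusion
  probability `p_incl`:
  `n_opt = [z_{1−α/2} · CV_trials / η]²`, and its inverse
  `η(n) = z_{1−α/2} · CV_trials / √n`.
* **Population mean** — the observed between-subject variance decomposes
  as `σ²_subjects(n) = σ²_subjects + σ²_trials/n`, giving
  `η(N, n) = z_{1−α/2} √(σ²_subjects + σ²_trials/n) / (μ_subjects √N)`.
* **Hypothesis testing** — expected t statistic and normal-approximation
  sample size for paired (asymptotic correlation `r`) and unpaired
  (`r = 0`) designs:
  `N_opt(n) = 2[σ²_subjects(1−r) + σ²_trials/n](z_{1−α/2}+z_{1−β})²/Δ²`.
* **Test–retest reliability** — attenuation of the observed correlation by
  finite trials, `r(n) = r·σ²_subjects/(σ²_subjects + σ²_trials/n)`, and
  its classical disattenuation.

Every relation is validated by a moment-matched lognormal Monte Carlo
engine (`simulate_*` functions), and `estimate_population()` /
`split_half_r()` / `planning_report()` extract all the planning parameters
from a recorded subject-by-trial amplitude table. The deprecated
`n_max`-bounded empirical definitions of the "optimal" trial count are also
implemented (`n_opt_ci()`, `n_opt_pctdiff()`) so their dependence on the
number of trials collected can be demonstrated.

## Worked example

A subject with `CV_trials = 0.5` needs about 96 trials for ±10% error with
95% probability — and cutting back to 30 or 20 trials costs precision:

```r
library(mepplan)
n_opt_trials(0.5, eta = 0.1)
#> [1] 96.03647
error_single(c(20, 30, 100), 0.5)
#> [1] 0.2191306 0.1789194 0.0979982
```

From data to a full plan (here a synthetic 20-subject × 100-trial table
drawn at the scale of real MEP recordings):

```r
fx  <- generate_fixture(N = 20, n = 100, mu_subjects = 1.48,
                        sigma_subjects = 0.57, sigma_trials = 1.01, seed = 42)
est <- estimate_population(fx)
est
#> <mep_population_estimate>
#>   20 subjects, 100 trials/subject (harmonic mean)
#>   mu_subjects        1.623 mV
#>   sigma_subjects(n)  0.7281 mV (observed)
#>   sigma_subjects     0.7213 mV (asymptotic)
#>   sigma_trials       0.9904 mV (pooled)
#>   CV_subjects        0.449
#>   CV_trials          0.713 (range 0.322-1.64)

planning_report(est, delta_means = c(1.23, 0.62), r = 0.61,
                z_sum = 2.80, n_grid = c(5, 10, 30, Inf))
#> <mep_planning_report>
#>   inputs: N = 20, mu = 1.62 mV, sigma_subjects = 0.721, sigma_trials = 0.99
#>
#> Trials per subject (eta = 0.1, p_incl = 0.95):
#> # A tibble: 3 × 4
#>   cv_trials which n_opt_raw n_opt
#>       <dbl> <chr>     <dbl> <dbl>
#> 1     0.713 mean      195.    196
#> 2     0.322 min        39.8    40
#> 3     1.64  max      1032.   1032
#>
#> Population-mean error vs trials:
#> # A tibble: 4 × 3
#>       n   eta eta_percent
#>   <dbl> <dbl>       <dbl>
#> 1     5 0.229        22.9
#> 2    10 0.212        21.2
#> 3    30 0.201        20.1
#> 4   Inf 0.195        19.5
#>
#> Subjects needed (mu1 = 1.23, mu2 = 0.62, r = 0.61):
#> # A tibble: 4 × 5
#>       n N_within_raw N_within N_between_raw N_between
#>   <dbl>        <dbl>    <dbl>         <dbl>     <dbl>
#> 1     5        16.8        17          30.2        31
#> 2    10        12.7        13          26.1        27
#> 3    30         9.93       10          23.3        24
#> 4   Inf         8.55        9          21.9        22
```

Reading the tables: this (synthetic) cohort's mean within-subject CV of
0.71 would need 196 trials per subject for ±10% single-subject precision,
yet the *population* mean error barely improves past 10 trials per subject
(21.2% at `n = 10` vs 19.5% with infinitely many) — precision there is
bought with subjects, not trials. To detect a halving of amplitude between
two stimulus intensities (means 1.23 vs 0.62 mV, asymptotic correlation
0.61), a within-subjects design with 10 trials per condition needs 13
subjects; a between-subjects design needs 27 per group.

Fitted objects have broom-style `tidy()`/`glance()` methods; simulated
curves have `autoplot()` methods overlaying the analytic prediction.

A thin command-line interface over the same functions ships in
`inst/cli/mepplan.R` (subcommands `plan-single`, `plan-population`,
`power`, `reliability`, `simulate`, `estimate`, `fixture`), writing
self-describing JSON reports and TSV curves:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mepplan.R", package = "mepplan"))')" \
  plan-single --cv 0.5 --eta 0.1 --p-incl 0.95 --rounding nearest
```

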