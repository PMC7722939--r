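Package: mepplan
Title: Trial and Sample-Size Planning for Motor Evoked Potential Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical planning tools for trial-averaged evoked-potential
    experiments, developed around transcranial magnetic stimulation (TMS)
    motor evoked potentials (MEPs). Provides closed-form relations between
    the number of trials per subject, the number of subjects, the within-
    and between-subject variability of single-trial amplitudes, estimation
    error, paired and unpaired t-test power, and test-retest reliability
    attenuation; a moment-matched lognormal Monte Carlo engine that checks
    every relation by simulation; and estimation routines that extract the
    planning parameters from a subject-by-trial amplitude table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
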