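Package: lungdepo
Title: Stochastic Whole-Lung Aerosol Deposition and Inhaler Repeatability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of inhaled drug particle deposition in a
    stochastic model of the human airways, driven by through-device inhalation
    maneuver parameters (inspiratory vital capacity, peak inspiratory flow,
    inhalation time, breath-hold time). Particles sampled from a lognormal
    aerodynamic size distribution are tracked through an extrathoracic filter
    and a stochastically sampled conducting and acinar airway path, depositing
    by inertial impaction, gravitational settling and Brownian diffusion.
    Includes a synthetic cohort generator emulating control and COPD maneuver
    statistics, Bland-Altman repeatability analysis (bias, limits of
    agreement, coefficient of repeatability), per-subject device ranking and
    group comparison tests, for comparing pressurized metered-dose and
    soft-mist inhalers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
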