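Package: dopplervti
Title: Carotid Doppler Velocity-Time-Integral Analysis for Valsalva Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of wearable continuous-wave Doppler
    ultrasound recordings during a standardized four-phase Valsalva maneuver.
    Provides a synthetic two-channel Doppler audio generator with programmable
    hemodynamics, short-time-Fourier-transform maximum-velocity envelope
    tracing by an integrated-power-percentile rule, cardiac-cycle segmentation
    with per-beat velocity time integrals (VTI) and heart rate, protocol
    windowing (baseline, peak inspiratory hold, recovery), the Doppler Shock
    Index (heart rate / carotid VTI) and shock index, paired t-tests on window
    changes, and sensitivity/specificity of detecting a 10 percent fall in
    reference aortic VTI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
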