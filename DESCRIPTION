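Package: circatap
Title: Ambulatory Circadian Monitoring Analysis with the Integrated TAP Variable
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of week-long ambulatory circadian monitoring (ACM)
    recordings from wearable sensors: wrist skin temperature, motor activity,
    body position, light exposure and environmental temperature. Builds the
    integrated TAP variable from normalized temperature (inverted), activity
    and position; computes the non-parametric circadian indexes (interdaily
    stability, intradaily variability, M10/L5 or M5/L10 levels, relative
    amplitude and its cohort-normalized form, and the circadian function
    index); derives night and day phase markers, the distance from the solar
    darkness center, and the Circadian Health Index; scores sleep diaries
    (binary sleep, sleep probability, corrected midsleep on free days and
    social jetlag); bins light exposure by daytime interval; and classifies
    subjects into early, neither and late chronotypes by percentiles of the
    TAP night phase marker. Includes a synthetic cohort generator with known
    ground truth so every pipeline stage can be validated without real
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    lubridate,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
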