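Package: insolegait
Title: Plantar-Pressure Insole Gait Analysis and Frailty Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing bilateral 7-sensor
    plantar-pressure insole recordings from standing balance and short
    walking trials. Provides a synthetic cohort generator emulating the
    insole signal model, stance-phase segmentation with strike/lift event
    detection, extraction of 182 gait and balance features across six
    categories (standing centre-of-pressure sway, frequency domain,
    per-sensor peak and area-under-curve statistics, single-foot
    centre-of-pressure trajectories, gait phase timing, and stance force
    envelope landmarks), and balanced random-forest classification of
    frailty and fall-history labels with repeated stratified
    cross-validation and impurity-based feature-importance ranking.
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
    grDevices,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
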