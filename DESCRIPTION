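Package: ciplanr
Title: Cochlear Implant Electrode Insertion Depth Prediction from Basal-Turn Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cochlear implant electrode insertion depth (angular and
    linear, at the first contact and at the silicone tip) from two basal-turn
    measurements taken on a CT cochlear view: the diameter A and the width B.
    Implements two analytical cochlear models -- a logarithmic-spiral cochlear
    duct length formula driven by A alone, and the Elliptic-Circular
    Approximation driven by A and B -- together with their inversions from
    linear depth to insertion angle. Includes postoperative validation
    (per-subject prediction errors and cohort summaries), observer-agreement
    statistics (Bland-Altman limits of agreement, two-way random-effects
    intraclass correlation with qualitative interpretation, paired Wilcoxon
    comparison of method variability), and a synthetic-cohort generator that
    emulates the measurement-noise structure of a two-observer,
    two-observation CT study design.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
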