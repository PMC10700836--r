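Package: acclimate
Title: Individualized Temperature Anomalies, Well-Being, and Climate Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how temperature anomalies relative to a
    person-specific historical reference affect subjective well-being, and
    whether acclimatization can keep pace with projected warming. Provides a
    synthetic-data generator for station weather, survey panels and climate
    scenario ensembles; inverse-distance interpolation of station weather to
    counties; construction of individualized (lifetime), fixed-period,
    preceding-years and cumulative-age reference temperatures; two-way
    fixed-effects panel estimation with survey weights and two-way
    cluster-robust covariance; and adaptation-aware projections of well-being
    impacts under emissions scenarios with continuously-updating versus fixed
    reference temperatures.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
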