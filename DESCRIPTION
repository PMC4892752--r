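Package: audbat
Title: Psychoacoustic Battery Simulation and Single-Case Analysis for
    Progressive Aphasia Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying central auditory processing in primary
    progressive aphasia (PPA) and similar clinical populations. Implements a
    12-task psychoacoustic battery covering pitch, rhythm/timing and timbre
    (frequency and spectro-temporal modulation), adaptive two-down one-up
    staircase testing against simulated psychometric-function observers,
    single-case deficit detection via the Crawford-Howell modified t-test with
    optional covariate adjustment, cohort-level statistics (normality
    screening and log-transform policy, one-sided group contrasts,
    Kruskal-Wallis subtype comparison with Tukey-Kramer post hocs,
    correlation analyses), pairwise linear support-vector-machine subtype
    classification with permutation testing, and principal-component factor
    analysis of a neuropsychological battery. A synthetic-cohort generator
    reproduces the statistical structure these analyses assume, so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nortest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
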