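Package: gobypass
Title: Personality-Informed Risk Assessment of Fish Passage over
    In-Stream Barriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing whether nonmigratory benthic fish, such
    as the invasive round goby, can ascend an in-stream barrier.  The
    package scores three personality traits (boldness, activity,
    asociability) from behavioral assay recordings, maps body length to
    critical swimming speed and endurance, applies an a-priori threshold
    decision matrix with a compensatory two-of-three personality rule,
    and fits a binary logit model with Hosmer-Lemeshow diagnostics, rank
    correlations, and all-subset AIC model selection.  A synthetic-data
    module generates cohorts, assay recordings, and barrier flow
    profiles with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
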