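Package: contactweave
Title: Diary-Based Social Contact Survey Analysis and Age-Structured Mixing Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diary-based social contact surveys of the
    POLYMOD family: reading and validating the conventional two-table
    (participants/contacts) layout plus coarse-band supplementary contact
    counts, computing per-participant sampling weights by raking (iterative
    proportional fitting) to population margins, estimating weighted
    age-structured mean contact matrices stratified by social setting and
    urban/rural residence with a reciprocity correction that equates total
    contact events between age groups at the population level, descriptive
    summaries (contact degree, duration, setting, intensity, distance and
    mobility) with the associated chi-squared machinery, and multivariable
    negative binomial regression of contact degree and total contact hours.
    A synthetic-survey generator with known ground truth makes every stage
    of the pipeline verifiable without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
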