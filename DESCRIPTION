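Package: truncsel
Title: Truncation Selection Across Multiple Sets of Genotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends the classical breeder's equation for truncation selection
    from a single population to multiple sets of candidates that differ in
    their means, genetic variances, and the accuracy of the selection
    criterion (phenotypic BLUEs or shrunken BLUPs). Provides closed-form
    expressions for the total selection response and the post-selection
    composition of the selected fraction, Lagrange-multiplier solvers for
    identical and optimal per-set truncation thresholds under a fixed
    selection budget, the percent improvement achievable by optimal
    thresholds, optimal per-pool selected proportions for factorials of
    hybrids selected on parental general combining ability (GCA), a
    Monte-Carlo oracle that validates the analytic results by simulation,
    parameter-grid scans, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
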